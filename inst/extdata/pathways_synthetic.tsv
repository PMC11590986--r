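pathway_id	name	parent_id	member_protein_ids	p_value
SPW-ROOT	Synthetic pathway root			1
SPW-B1	Gap junction trafficking and regulation	SPW-ROOT		1
SPW-B2	Ion homeostasis	SPW-ROOT		1
SPW-B3	Muscle contraction	SPW-ROOT		1
SPW-B4	Cellular responses to stress	SPW-ROOT		1
SPW-001	Gap junction assembly	SPW-B1	P80076|P80086|P63316|P29474|P80016|P80061|P80015	0.0545055
SPW-002	Gap junction degradation	SPW-B2	P80025|P80062|P14780|P80047|P80045|P80033|P80068|Q16566	0.00174812
SPW-003	Oligomerization of connexins into connexons	SPW-B3	P80108|P80021|P80037|P80107|P80098|P80051|P80062|P80018|P80011|P80025|P80058	0.00259105
SPW-004	Transport of connexins along the secretory pathway	SPW-B4	P05067|P80108|Q6J4K2|P80062	0.0590406
SPW-005	Transport of connexons to the plasma membrane	SPW-B1	P80009|Q8IYU8|P80076|P80106|P80006|Q9BPX6|P80105|P80065|P45379|P80087|P80089|P80046|P80022|P80015|P80049	0.0335451
SPW-006	Cardiac conduction	SPW-B2	P05067|P80074|P80051	0.226709
SPW-007	Ion channel transport	SPW-B3	P80024|P80017|P80009|Q13557|P80037	0.149671
SPW-008	Stimuli-sensing channels	SPW-B4	P80025|P80104|P80035|P80039|P80051	0.0752167
SPW-009	Calcium dynamics	SPW-B1	P80105|P80018|P45379|P80102|P80026|P80038|P80017|P80037|P80005|P80061|P80104	0.0117616
SPW-010	Reduction of cytosolic calcium levels	SPW-B2	P63316|P62158|P80001|P80100|P80078|P80042	0.0272647
SPW-011	Striated muscle contraction	SPW-B3	P80033|P80108|P80001|Q13557|P80011|Q6J4K2|P14780|P05067|P80012|P80075|P80038	0.0539575
SPW-012	Smooth muscle contraction	SPW-B4	P80089|Q16566|P80092|P14780|P80058|P80099|P80062|P80074|P80075	0.00953198
SPW-013	Detoxification of reactive oxygen species	SPW-B1	P80031|O14958|P80078|P80080|P05067|Q13936|P80025|P80096|P80071	0.0564826
SPW-014	Cellular response to heat stress	SPW-B2	P80056|P80052|Q13557|P80079|P80103|P80072|P80055	0.0654571
SPW-015	Synthetic leaf pathway 1	SPW-B3	P80054|P80076|P80005|P80001|P80041|P80092|P80037|P80095|P63316	1.65562e-06
SPW-016	Synthetic leaf pathway 2	SPW-B4	O14958|P63316|P80083|P80085	0.000266881
SPW-017	Synthetic leaf pathway 3	SPW-B1	P80003|P80028|Q9BPX6|P80085|P80036|P80045|P80096|P80040|P62158|P80079|P80018|P80021|P26678	0.000412659
SPW-018	Synthetic leaf pathway 4	SPW-B2	P80079|P80013|P80078|P80092|P80073|P80080|P80012|P80004|P80006|P80041	0.275271
SPW-019	Synthetic leaf pathway 5	SPW-B3	P80081|P80006|P80086	0.0455605
SPW-020	Synthetic leaf pathway 6	SPW-B4	P80056|P80031|P80083|P80012|P80099|P80093|P80051|P80075|P80092|P80068|P80049	0.0858809
SPW-021	Synthetic leaf pathway 7	SPW-B1	P80007|P80049|P80039|P80009|P80100|P80080|P80010|P80023|P80096	0.138212
SPW-022	Synthetic leaf pathway 8	SPW-B2	P05067|P80072|P80073|P80019|Q9BPX6|P80017|P80100|P80011|P80077	0.00800946
SPW-023	Synthetic leaf pathway 9	SPW-B3	P80035|P80034|P80076|P80071|P80030|P80016|P80080|P29474|P80098|P80013|P80042|P80073|P80017|P80048|P80088	0.0271185
SPW-024	Synthetic leaf pathway 10	SPW-B4	P80086|P16615|P80098	4.57573e-05
SPW-025	Synthetic leaf pathway 11	SPW-B1	P80054|P80003|P80067|P80031|P80039|P80011	0.00218143
SPW-026	Synthetic leaf pathway 12	SPW-B2	P16615|P80038|P80103|P80101|P80021|P80032|P80007|P80068	2.60908e-07
SPW-027	Synthetic leaf pathway 13	SPW-B3	P80099|P80014|P80106|P80067|Q6J4K2|P80001|P80002|Q92736|P80046|P80090|P80051|P80059|P80023|P80078	0.0356802
SPW-028	Synthetic leaf pathway 14	SPW-B4	P32418|P80039|P80105|P80080|P80040|P80099|P80056|P80076|P80077|P80044|P80049	0.000195041
SPW-029	Synthetic leaf pathway 15	SPW-B1	P80023|P29474|P80084|P80042|P80080|P80029|P80041|P80100	0.000544608
SPW-030	Synthetic leaf pathway 16	SPW-B2	P80041|P80058|P80015|P80057|Q92736|P80072|P17302|P80091|P80001|P80028|P80081|P80093|P80108|Q8NE86	0.0479658
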