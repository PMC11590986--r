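"descriptor_id","name","phase","subcategory"
"D200001","Reactive Oxygen Species","IOS","reactive oxygen species"
"D200002","Superoxides","IOS","reactive oxygen species"
"D200003","Hydroxyl Radical","IOS","reactive oxygen species"
"D200004","Hydrogen Peroxide","IOS","reactive oxygen species"
"D200005","Singlet Oxygen","IOS","reactive oxygen species"
"D200006","Free Radicals","IOS","reactive oxygen species"
"D200007","Nitric Oxide","IOS","reactive nitrogen species"
"D200008","Peroxynitrous Acid","IOS","reactive nitrogen species"
"D200009","Reactive Nitrogen Species","IOS","reactive nitrogen species"
"D200010","Aldehydes","IOS","reactive aldehydes"
"D200011","Acrolein","IOS","reactive aldehydes"
"D200012","Malondialdehyde","IOS","reactive aldehydes"
"D200101","Glutathione","MOS","redox metabolites"
"D200102","Glutathione Disulfide","MOS","redox metabolites"
"D200103","NAD","MOS","redox metabolites"
"D200104","NADP","MOS","redox metabolites"
"D200105","Uric Acid","MOS","redox metabolites"
"D200106","Bilirubin","MOS","redox metabolites"
"D200107","Antioxidants","MOS","antioxidants"
"D200108","Ascorbic Acid","MOS","antioxidants"
"D200109","Vitamin A","MOS","antioxidants"
"D200110","Vitamin E","MOS","antioxidants"
"D200111","Carotenoids","MOS","antioxidants"
"D200112","Melatonin","MOS","antioxidants"
"D200113","Coenzyme Q10","MOS","antioxidants"
"D200114","Superoxide Dismutase","MOS","antioxidant enzymes"
"D200115","Catalase","MOS","antioxidant enzymes"
"D200116","Glutathione Peroxidase","MOS","antioxidant enzymes"
"D200117","Glutathione Reductase","MOS","antioxidant enzymes"
"D200118","Glutathione Transferase","MOS","antioxidant enzymes"
"D200119","Peroxiredoxins","MOS","antioxidant enzymes"
"D200120","Heme Oxygenase-1","MOS","antioxidant enzymes"
"D200121","Thioredoxin Reductases","MOS","antioxidant enzymes"
"D200122","Sulfiredoxin","MOS","antioxidant enzymes"
"D200123","Methionine Sulfoxide Reductases","MOS","antioxidant enzymes"
"D200124","Paraoxonase","MOS","antioxidant enzymes"
"D200125","Ceruloplasmin","MOS","antioxidant enzymes"
"D200126","Thioredoxins","MOS","redox regulating proteins"
"D200127","Ferritins","MOS","redox regulating proteins"
"D200128","Metallothionein","MOS","redox regulating proteins"
"D200129","NF-E2-Related Factor 2","MOS","redox regulating proteins"
"D200130","Kelch-Like ECH-Associated Protein 1","MOS","redox regulating proteins"
"D200131","Sirtuins","MOS","redox regulating proteins"
"D200132","Forkhead Box Protein O1","MOS","redox regulating proteins"
"D200133","Synthetic Redox Modulator 1","MOS","redox metabolites"
"D200134","Synthetic Redox Modulator 2","MOS","antioxidants"
"D200135","Synthetic Redox Modulator 3","MOS","antioxidant enzymes"
"D200136","Synthetic Redox Modulator 4","MOS","redox regulating proteins"
"D200137","Synthetic Redox Modulator 5","MOS","redox metabolites"
"D200138","Synthetic Redox Modulator 6","MOS","antioxidants"
"D200139","Synthetic Redox Modulator 7","MOS","antioxidant enzymes"
"D200140","Synthetic Redox Modulator 8","MOS","redox regulating proteins"
"D200141","Synthetic Redox Modulator 9","MOS","redox metabolites"
"D200142","Synthetic Redox Modulator 10","MOS","antioxidants"
"D200143","Synthetic Redox Modulator 11","MOS","antioxidant enzymes"
"D200144","Synthetic Redox Modulator 12","MOS","redox regulating proteins"
"D200145","Synthetic Redox Modulator 13","MOS","redox metabolites"
"D200146","Synthetic Redox Modulator 14","MOS","antioxidants"
"D200147","Synthetic Redox Modulator 15","MOS","antioxidant enzymes"
"D200148","Synthetic Redox Modulator 16","MOS","redox regulating proteins"
"D200149","Synthetic Redox Modulator 17","MOS","redox metabolites"
"D200150","Synthetic Redox Modulator 18","MOS","antioxidants"
"D200151","Synthetic Redox Modulator 19","MOS","antioxidant enzymes"
"D200152","Synthetic Redox Modulator 20","MOS","redox regulating proteins"
"D200153","Synthetic Redox Modulator 21","MOS","redox metabolites"
"D200154","Synthetic Redox Modulator 22","MOS","antioxidants"
"D200155","Synthetic Redox Modulator 23","MOS","antioxidant enzymes"
"D200156","Synthetic Redox Modulator 24","MOS","redox regulating proteins"
"D200157","Synthetic Redox Modulator 25","MOS","redox metabolites"
"D200201","Protein Carbonylation","OOS","protein oxidation"
"D200202","Lipid Peroxidation","OOS","lipid peroxidation products"
"D200203","4-Hydroxynonenal","OOS","lipid peroxidation products"
"D200204","Oxidized LDL","OOS","lipid peroxidation products"
"D200205","8-Hydroxy-2'-Deoxyguanosine","OOS","oxidative DNA damage"
"D200206","Protein Nitration Products","OOS","nitrative DNA damage"
"D200007","Nitric Oxide","MOS","redox metabolites"
"D200012","Malondialdehyde","OOS","lipid peroxidation products"
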