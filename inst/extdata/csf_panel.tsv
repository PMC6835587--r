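name	formula	n_2h	n_13c	n_15n	group	panel	silc
Alanine	C3H7NO2	0	0	0	amino_acids	TRUE	FALSE
Arginine	C6H14N4O2	0	0	0	amino_acids	TRUE	FALSE
Asparagine	C4H8N2O3	0	0	0	amino_acids	TRUE	FALSE
Aspartic acid	C4H7NO4	0	0	0	amino_acids	TRUE	FALSE
Cysteine	C3H7NO2S	0	0	0	amino_acids	TRUE	FALSE
Cystine	C6H12N2O4S2	0	0	0	amino_acids	TRUE	FALSE
Glutamic acid	C5H9NO4	0	0	0	amino_acids	TRUE	FALSE
Glutamine	C5H10N2O3	0	0	0	amino_acids	TRUE	FALSE
Glycine	C2H5NO2	0	0	0	amino_acids	TRUE	FALSE
Histidine	C6H9N3O2	0	0	0	amino_acids	TRUE	FALSE
Homoarginine	C7H16N4O2	0	0	0	amino_acids	TRUE	FALSE
Homocarnosine	C10H16N4O3	0	0	0	amino_acids	TRUE	FALSE
(Iso)leucine	C6H13NO2	0	0	0	amino_acids	TRUE	FALSE
Lysine	C6H14N2O2	0	0	0	amino_acids	TRUE	FALSE
Methionine	C5H11NO2S	0	0	0	amino_acids	TRUE	FALSE
Phenylalanine	C9H11NO2	0	0	0	amino_acids	TRUE	FALSE
Proline	C5H9NO2	0	0	0	amino_acids	TRUE	FALSE
Serine	C3H7NO3	0	0	0	amino_acids	TRUE	FALSE
Threonine	C4H9NO3	0	0	0	amino_acids	TRUE	FALSE
Tryptophan	C11H12N2O2	0	0	0	amino_acids	TRUE	FALSE
Tyrosine	C9H11NO3	0	0	0	amino_acids	TRUE	FALSE
Ornithine	C5H12N2O2	0	0	0	amino_acids	TRUE	FALSE
Taurine	C2H7NO3S	0	0	0	amino_acids	TRUE	FALSE
Valine	C5H11NO2	0	0	0	amino_acids	TRUE	FALSE
3-Methoxytyrosine	C10H13NO4	0	0	0	neurotransmitters	TRUE	FALSE
5-Hydroxyindoleacetic acid	C10H9NO3	0	0	0	neurotransmitters	TRUE	FALSE
5-Hydroxytryptophan	C11H12N2O3	0	0	0	neurotransmitters	TRUE	FALSE
5-Methyltetrahydrofolic acid	C20H25N7O6	0	0	0	neurotransmitters	TRUE	FALSE
Dopamine	C8H11NO2	0	0	0	neurotransmitters	TRUE	FALSE
Dopamine 4-sulfate	C8H11NO5S	0	0	0	neurotransmitters	TRUE	FALSE
Dopamine glucuronide	C14H19NO8	0	0	0	neurotransmitters	TRUE	FALSE
Epinephrine	C9H13NO3	0	0	0	neurotransmitters	TRUE	FALSE
Epinephrine glucuronide	C15H21NO9	0	0	0	neurotransmitters	TRUE	FALSE
Epinephrine sulfate	C9H13NO6S	0	0	0	neurotransmitters	TRUE	FALSE
Homovanillic acid	C9H10O4	0	0	0	neurotransmitters	TRUE	FALSE
Gamma-aminobutyric acid	C4H9NO2	0	0	0	neurotransmitters	TRUE	FALSE
l-Dopa	C9H11NO4	0	0	0	neurotransmitters	TRUE	FALSE
Methoxyhydroxyphenylglycol	C9H12O4	0	0	0	neurotransmitters	TRUE	FALSE
n-Acetylserotonin	C12H14N2O2	0	0	0	neurotransmitters	TRUE	FALSE
Norepinephrine	C8H11NO3	0	0	0	neurotransmitters	TRUE	FALSE
Norepinephrine sulfate	C8H11NO6S	0	0	0	neurotransmitters	TRUE	FALSE
Serotonin	C10H12N2O	0	0	0	neurotransmitters	TRUE	FALSE
Vanillactic acid	C10H12O5	0	0	0	neurotransmitters	TRUE	FALSE
Vanillylmandelic acid	C9H10O5	0	0	0	neurotransmitters	TRUE	FALSE
5-Hydroxymethyluracil	C5H6N2O3	0	0	0	purines_pyrimidines	TRUE	FALSE
Adenine	C5H5N5	0	0	0	purines_pyrimidines	TRUE	FALSE
Adenosine	C10H13N5O4	0	0	0	purines_pyrimidines	TRUE	FALSE
AICAR	C9H15N4O8P	0	0	0	purines_pyrimidines	TRUE	FALSE
Deoxyadenosine	C10H13N5O3	0	0	0	purines_pyrimidines	TRUE	FALSE
Deoxyinosine	C10H12N4O4	0	0	0	purines_pyrimidines	TRUE	FALSE
Dihydrothymine	C5H8N2O2	0	0	0	purines_pyrimidines	TRUE	FALSE
Dihydrouracil	C4H6N2O2	0	0	0	purines_pyrimidines	TRUE	FALSE
Guanosine	C10H13N5O5	0	0	0	purines_pyrimidines	TRUE	FALSE
Hypoxanthine	C5H4N4O	0	0	0	purines_pyrimidines	TRUE	FALSE
Inosine	C10H12N4O5	0	0	0	purines_pyrimidines	TRUE	FALSE
Orotic acid	C5H4N2O4	0	0	0	purines_pyrimidines	TRUE	FALSE
SAICAR	C13H19N4O12P	0	0	0	purines_pyrimidines	TRUE	FALSE
Succinyladenosine	C14H17N5O8	0	0	0	purines_pyrimidines	TRUE	FALSE
Thymidine	C10H14N2O5	0	0	0	purines_pyrimidines	TRUE	FALSE
Thymine	C5H6N2O2	0	0	0	purines_pyrimidines	TRUE	FALSE
Uracil	C4H4N2O2	0	0	0	purines_pyrimidines	TRUE	FALSE
Uric acid	C5H4N4O3	0	0	0	purines_pyrimidines	TRUE	FALSE
Uridine	C9H12N2O6	0	0	0	purines_pyrimidines	TRUE	FALSE
Xanthine	C5H4N4O2	0	0	0	purines_pyrimidines	TRUE	FALSE
n-Acetylaspartylglutamic acid	C11H16N2O8	0	0	0	organic_acids	TRUE	FALSE
2-Methylcitric acid	C7H10O7	0	0	0	organic_acids	TRUE	FALSE
3-Hydroxybutyric acid	C4H8O3	0	0	0	organic_acids	TRUE	FALSE
3-Hydroxyisovaleric acid	C5H10O3	0	0	0	organic_acids	TRUE	FALSE
4-Guanidinobutanoic acid	C5H11N3O2	0	0	0	organic_acids	TRUE	FALSE
Acetoacetic acid	C4H6O3	0	0	0	organic_acids	TRUE	FALSE
Cis-Aconitic acid	C6H6O6	0	0	0	organic_acids	TRUE	FALSE
Citric acid	C6H8O7	0	0	0	organic_acids	TRUE	FALSE
Fumaric acid	C4H4O4	0	0	0	organic_acids	TRUE	FALSE
Lactic acid	C3H6O3	0	0	0	organic_acids	TRUE	FALSE
Malic acid	C4H6O5	0	0	0	organic_acids	TRUE	FALSE
n-Acetylaspartic acid	C6H9NO5	0	0	0	organic_acids	TRUE	FALSE
Oxalacetic acid	C4H4O5	0	0	0	organic_acids	TRUE	FALSE
Propionic acid	C3H6O2	0	0	0	organic_acids	TRUE	FALSE
Pyruvic acid	C3H4O3	0	0	0	organic_acids	TRUE	FALSE
Succinic acid	C4H6O4	0	0	0	organic_acids	TRUE	FALSE
Creatine	C4H9N3O2	0	0	0	creatine_metabolism	TRUE	FALSE
Creatinine	C4H7N3O	0	0	0	creatine_metabolism	TRUE	FALSE
Guanidoacetic acid	C3H7N3O2	0	0	0	creatine_metabolism	TRUE	FALSE
Phosphocreatine	C4H10N3O5P	0	0	0	creatine_metabolism	TRUE	FALSE
Phosphocreatinine	C4H8N3O4P	0	0	0	creatine_metabolism	TRUE	FALSE
Folic acid	C19H19N7O6	0	0	0	vitamers	TRUE	FALSE
Thiamine	C12H16N4OS	0	0	0	vitamers	TRUE	FALSE
Thiamine monophosphate	C12H18N4O4PS	0	0	0	vitamers	TRUE	FALSE
Thiamine pyrophosphate	C12H19N4O7P2S	0	0	0	vitamers	TRUE	FALSE
Thiamine triphosphate	C12H20N4O10P3S	0	0	0	vitamers	TRUE	FALSE
7,8-Dihydroneopterin	C9H13N5O4	0	0	0	pterines	TRUE	FALSE
Dihydrobiopterin	C9H13N5O3	0	0	0	pterines	TRUE	FALSE
Neopterin	C9H11N5O4	0	0	0	pterines	TRUE	FALSE
Biopterin	C9H11N5O3	0	0	0	pterines	TRUE	FALSE
Tetrahydroneopterin	C9H15N5O4	0	0	0	pterines	TRUE	FALSE
Tetrahydrobiopterin	C9H15N5O3	0	0	0	pterines	TRUE	FALSE
Saccharopine	C11H20N2O6	0	0	0	other	TRUE	FALSE
s-Adenosylhomocysteine	C14H20N6O5S	0	0	0	methyldonor	TRUE	FALSE
s-Adenosylmethionine	C15H22N6O5S	0	0	0	methyldonor	TRUE	FALSE
Pipecolic acid	C6H11NO2	0	0	0	vitamin_b6	TRUE	FALSE
Pyridoxal	C8H9NO3	0	0	0	vitamin_b6	TRUE	FALSE
Pyridoxal 5-phosphate	C8H10NO6P	0	0	0	vitamin_b6	TRUE	FALSE
Pyridoxamine	C8H12N2O2	0	0	0	vitamin_b6	TRUE	FALSE
Pyridoxamine 5-phosphate	C8H13N2O5P	0	0	0	vitamin_b6	TRUE	FALSE
Pyridoxine	C8H11NO3	0	0	0	vitamin_b6	TRUE	FALSE
Pyridoxine 5-phosphate	C8H12NO6P	0	0	0	vitamin_b6	TRUE	FALSE
Alpha-aminoadipic acid delta-semialdehyde	C6H11NO3	0	0	0	vitamin_b6	TRUE	FALSE
15N;2-13C-glycine	C2H5NO2	0	2	1	silc	FALSE	TRUE
2H4-alanine	C3H7NO2	4	0	0	silc	FALSE	TRUE
2H3-leucine	C6H13NO2	3	0	0	silc	FALSE	TRUE
2H3-methionine	C5H11NO2S	3	0	0	silc	FALSE	TRUE
13C6-phenylalanine	C9H11NO2	0	6	0	silc	FALSE	TRUE
13C6-tyrosine	C9H11NO3	0	6	0	silc	FALSE	TRUE
2H3-aspartate	C4H7NO4	3	0	0	silc	FALSE	TRUE
2H3-glutamate	C5H9NO4	3	0	0	silc	FALSE	TRUE
2H2-ornithine	C5H12N2O2	2	0	0	silc	FALSE	TRUE
2H2-citrulline	C6H13N3O3	2	0	0	silc	FALSE	TRUE
2H4;13C-arginine	C6H14N4O2	4	1	0	silc	FALSE	TRUE
2H8-valine	C5H11NO2	8	0	0	silc	FALSE	TRUE
2H9-carnitine	C7H15NO3	9	0	0	silc	FALSE	TRUE
2H3-acetylcarnitine	C9H17NO4	3	0	0	silc	FALSE	TRUE
2H3-propionylcarnitine	C10H19NO4	3	0	0	silc	FALSE	TRUE
2H3-butyrylcarnitine	C11H21NO4	3	0	0	silc	FALSE	TRUE
2H9-isovalerylcarnitine	C12H23NO4	9	0	0	silc	FALSE	TRUE
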