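analyte,atc_code,drug_class,adq_g,excreted_fraction,loq_ng_l
Azithromycin,J01FA10,Macrolide antibiotic,0.5,0.85,1
Cefotaxime,J01DD01,Third-generation cephalosporin antibiotic,4,0.85,10
Ciprofloxacin,J01MA02,Fluoroquinolone antibiotic,0.8,1.00,5
Clarithromycin,J01FA09,Macrolide antibiotic,0.5,0.55,4
Doxycycline,J01AA02,Tetracycline antibiotic,0.1,0.80,1
Erythromycin,J01FA01,Macrolide antibiotic,1,1.00,4
Norfloxacin,J01MA06,Fluoroquinolone antibiotic,0.8,0.90,1
Ofloxacin,J01MA01,Fluoroquinolone antibiotic,0.4,0.98,4
Oxytetracycline,J01AA06,Tetracycline antibiotic,1,0.35,4
Sulfamethoxazole,J01EC01,Sulfonamide antibiotic,0.8,1.00,2
Trimethoprim,J01EA01,Dihydrofolate reductase inhibitor antibiotic,0.4,1.00,1
Naphazoline,R01AA08,Vasoconstrictor decongestant,0.4,0.90,1
Oxymetazoline,R01AA05,Vasoconstrictor decongestant,0.4,0.35,7
Xylometazoline,R01AA07,Vasoconstrictor decongestant,0.8,0.90,11
Oseltamivir carboxylate,J05AH02,Neuraminidase inhibitor antiviral,0.2,0.80,2
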