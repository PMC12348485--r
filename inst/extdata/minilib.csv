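compound_id,name,formula,class,smiles,source
arginine,Arginine,C6H14N4O2,other,NC(CCCNC(N)=N)C(O)=O,primary metabolite
glutathione,Glutathione,C10H17N3O6S,other,NC(CCC(=O)NC(CS)C(=O)NCC(O)=O)C(O)=O,primary metabolite
norcoclaurine,Norcoclaurine,C16H17NO3,alkaloid,Oc1ccc(CC2NCCc3cc(O)c(O)cc23)cc1,benzylisoquinoline monomer
coclaurine,Coclaurine,C17H19NO3,alkaloid,COc1cc2CCNC(Cc3ccc(O)cc3)c2cc1O,benzylisoquinoline monomer
n_norarmepavine,N-Norarmepavine,C18H21NO3,alkaloid,,benzylisoquinoline monomer
n_methylisococlaurine,N-Methylisococlaurine,C18H21NO3,alkaloid,,benzylisoquinoline monomer
n_methylcoclaurine,N-Methylcoclaurine,C18H21NO3,alkaloid,,benzylisoquinoline monomer
armepavine,Armepavine,C19H23NO3,alkaloid,COc1cc2CCN(C)C(Cc3ccc(O)cc3)c2cc1OC,benzylisoquinoline monomer
nuciferine,Nuciferine,C19H21NO2,alkaloid,,aporphine
pronuciferine,Pronuciferine,C19H21NO3,alkaloid,,proaporphine
xylopine,Xylopine,C18H17NO3,alkaloid,,aporphine
lanuginosine,Lanuginosine,C17H9NO5,alkaloid,,oxoaporphine
liensinine,Liensinine,C37H42N2O6,alkaloid,,bisbenzylisoquinoline dimer of mature plumule
isoliensinine,Isoliensinine,C37H42N2O6,alkaloid,,bisbenzylisoquinoline dimer of mature plumule
neferine,Neferine,C38H44N2O6,alkaloid,,bisbenzylisoquinoline dimer of mature plumule
kaempferol,Kaempferol,C15H10O6,flavonoid,,flavonol aglycone
catechin,Catechin,C15H14O6,flavonoid,,flavan-3-ol
taxifolin,Taxifolin,C15H12O7,flavonoid,,dihydroflavonol
epitaxifolin,Epitaxifolin,C15H12O7,flavonoid,,dihydroflavonol isomer of taxifolin
astragalin,Astragalin,C21H20O11,flavonoid,,kaempferol 3-O-glucoside
vitexin,Vitexin,C21H20O10,flavonoid,,apigenin 8-C-glucoside
myricetin_3_glc,Myricetin 3-O-glucoside,C21H20O13,flavonoid,,flavonol glycoside
syringetin_3_glc,Syringetin 3-O-glucoside,C23H24O13,flavonoid,,flavonol glycoside
rutin,Rutin,C27H30O16,flavonoid,,quercetin 3-O-rutinoside
luteolin_7_rut,Luteolin 7-O-rutinoside,C27H30O15,flavonoid,,flavone glycoside
schaftoside,Schaftoside,C26H28O14,flavonoid,,apigenin 6-C-glucosyl-8-C-arabinoside
palmitic_acid,Palmitic acid,C16H32O2,fatty acid,CCCCCCCCCCCCCCCC(O)=O,membrane lipid
oleic_acid,Oleic acid,C18H34O2,fatty acid,,membrane lipid
linolenic_acid,Linolenic acid,C18H30O2,fatty acid,,signalling lipid
anisic_acid,Anisic acid,C8H8O3,phenolic acid,COc1ccc(cc1)C(O)=O,
protocatechuic_acid,Protocatechuic acid,C7H6O4,phenolic acid,,
n_feruloyltyramine,N-Feruloyltyramine,C18H19NO4,phenylpropanoid,,hydroxycinnamic acid amide
dihydrophaseic_glc,Dihydrophaseic acid 3'-O-glucoside,C21H32O10,apocarotenoid,,abscisic acid metabolite
methyladenosine_5,5'-O-Methyladenosine,C11H15N5O4,other,,nucleoside
pheophytin_a,Pheophytin A,C55H74N4O5,other,,chlorophyll degradation product
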