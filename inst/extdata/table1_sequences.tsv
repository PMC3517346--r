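organism	acronym	class	evidence	accession
Ailuropoda melanoleuca	Am	SMO	predicted protein	GenBank:EFB25976
Anolis carolinensis	An	SMO	predicted protein	ID:ENSACAP00000000096
Bos taurus	Bt	SMO	protein	Swiss-Prot:Q865R1
Callithrix jacchus	Cj	SMO	predicted protein	ID:ENSCJAP00000039556
Canis familiaris	Cf	SMO	predicted protein	GenBank:XP_860548
Cavia porcellus	Cp	SMO	predicted protein	ID:ENSCPOP00000015071
Danio rerio	Dr	SMO	protein	Swiss-Prot:Q6NYY8
Dipodomys ordii	Do	SMO	predicted protein	ID:ENSDORP00000002003
Equus caballus	Eq	SMO	predicted protein	GenBank:XP_001495419
Felis catus	Fc	SMO	predicted protein	ID:ENSFCAP00000002991
Gallus gallus	Gg	SMO	predicted protein	GenBank:XP_420872
Gasterosteus aculeatus	Ga	SMO	predicted protein	ID:ENSGACP00000023283
Gorilla gorilla	Go	SMO	predicted protein	ID:ENSGGOP00000018695
Homo sapiens	Hs	SMO	protein	Swiss-Prot:Q99K82
Loxodonta africana	La	SMO	predicted protein	ID:ENSLAFP00000010450
Macaca fascicularis	Mf	SMO	predicted protein	GeneBank:BAE88223
Macropus eugenii	Me	SMO	predicted protein	ID:ENSMEUP00000000797
Microcebus murinus	Mu	SMO	predicted protein	ID:ENSMICP00000006250
Monodelphis domestica	Md	SMO	predicted protein	GenBank:XP_001380279
Mus musculus	Mm	SMO	protein	Swiss-Prot:NP_663508
Myosotis lucifugus	Ml	SMO	predicted protein	ID:ENSMLUP00000014140
Nomascus leucogenys	Nl	SMO	predicted protein	ID:ENSNLEG00000007689
Ornithorhyncus anatinus	Oa	SMO	predicted protein	GenBank:XP_001516006
Oryctogalus cuniculus	Oc	SMO	predicted protein	ID:ENSOCUP00000006931
Oryzias latipes	Ol	SMO	predicted protein	ID:ENSORLP00000007986
Pan troglodytes	Pt	SMO	protein	Swiss-Prot:XP_514493
Pongo abelii	Pa	SMO	predicted protein	GenBank:XP_002830111
Rattus norvegicus	Rn	SMO	protein	Swiss-Prot:XP_001079707
Sus scrofa	Ss	SMO	predicted protein	GenBank:XR_04566
Taeniopygia guttata	Tg	SMO	predicted protein	GenBank:XP_002189301
Takifugu rubripes	Tr	SMO	predicted protein	ID:ENSTRUP00000003466
Tarsius syrinchtae	Ts	SMO	predicted protein	ID:ENSTSYP00000002870
Tetraodon nigroviridis	Tn	SMO	predicted protein	ID:ENSTNIP00000001941
Tursiops truncatus	Tt	SMO	predicted protein	ID:ENSTTRP00000009415
Xenopus laevis	Xl	SMO	protein	Swiss-Prot:Q6INQ4
Xenopus tropicalis	Xt	SMO	protein	Swiss-Prot:Q28C17
Anolis carolinensis	An	APAO	predicted protein	XP_003225445
Bos taurus	Bt	APAO	protein	Swiss-Prot:Q865R1
Callithrix jacchus	Cj	APAO	predicted protein	ID:ENSCJAP00000009627
Cavia porcellus	Cp	APAO	predicted protein	ID:ENSCPOP00000010900
Danio rerio	Dr	APAO	predicted protein	GenBank:XP_690593
Equus caballus	Eq	APAO	predicted protein	ID:ENSECAP00000000093
Gallus gallus	Gg	APAO	predicted protein	ID:ENSGALP00000005619
Gasterosteus aculeatus	Ga	APAO	predicted protein	GenBank:BT027282
Gorilla gorilla	Go	APAO	predicted protein	ID:ENSGGOP00000004628
Homo sapiens	Hs	APAO	protein	Swiss-Prot:Q6QHF9-1
Loxodonta africana	La	APAO	predicted protein	ID:ENSLAFP00000007186
Macaca mulatta	Ml	APAO	predicted protein	ID:ENSMMUP00000008331
Macropus eugenii	Me	APAO	predicted protein	ID:ENSMEUP00000004459
Monodelphis domestica	Md	APAO	predicted protein	ID:ENSMODP00000013113
Mus musculus	Mm	APAO	protein	Swiss-Prot:Q4GX45
Oryzias latipes	Ol	APAO	predicted protein	ID:ENSORLP00000011447
Pongo pygmaeus	Pp	APAO	predicted protein	ID:ENSPPYP00000003262
Procavia capensis	Pc	APAO	predicted protein	ID:ENSPCAP00000005028
Pteropus vampyrus	Pv	APAO	predicted protein	ID:ENSPVAG00000002682
Rattus norvegicus	Rn	APAO	protein	Swiss-Prot:Q7TPJ4
Taeniopygia guttata	Tg	APAO	predicted protein	GenBank:XP_002186801
Takifugu rubripes	Tr	APAO	predicted protein	ID:ENSTRUP00000035024
Tetraodon nigroviridis 1	Tn1	APAO	predicted protein	ID:ENSTNIP00000019636
Tetraodon nigroviridis 2	Tn2	APAO	predicted protein	ID:ENSTNIP00000002385
Tursiops truncatus	Tt	APAO	predicted protein	ID:ENSTTRP00000014996
Xenopus laevis	Xl	APAO	protein	Swiss-Prot:Q5U4L6
Anopheles gambia	Ag	PAO	predicted protein	XP_312316.3
Apis mellifera	Am	PAO	predicted protein	GenBank:XP_001122522
Branchiostoma floridae 1	Bf1	PAO	predicted protein	GenBank:XP_002225568
Branchiostoma floridae 2	Bf2	PAO	predicted protein	GenBank:XP_002606976
Caenorhabditis elegans	Ce	PAO	predicted protein	GenBank:NP_001023872
Ciona intestinalis	Ci	PAO	predicted protein	XP_002132119
Drosophila melanogaster	Dm	PAO	protein	Swiss-Prot:Q9VHN8
Nasonia vitripennis	Nv	PAO	predicted protein	XP_001599761
Nematostella vectensis	Ne	PAO	predicted protein	GenBank:XP_001626025
Pediculus humanus corporis	Ph	PAO	predicted protein	GenBank:EEB13427
Saccharomyces cerevisiae	Sc	PAO	protein	GenBank:YDL174C
Strongylocentrotus purpuratus	Sp	PAO	predicted protein	GenBank:XP_001195328
Tribolium castaneum	Tc	PAO	predicted protein	GenBank:XP_971067
Trichoplax adhaerens	Ta	PAO	predicted protein	GenBank:XP_002107802
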