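uniprot_id	gene_name	protein_name	on_rabbit_x	in_first_target_list
Q9BYF1	ACE2	Angiotensin-converting enzyme 2	TRUE	TRUE
Q8IZP9	ADGRG2	Adhesion G-protein-coupled receptor G2	TRUE	TRUE
Q4VCS5	AMOT	Angiomotin	TRUE	TRUE
P23352	ANOS1	Anosmin-1	FALSE	FALSE
Q9BUR5	APOO	MICOS complex subunit MIC26	TRUE	FALSE
Q8NB49	ATP11C	Phospholipid-transporting ATPase IG	FALSE	FALSE
Q16720	ATP2B3	Plasma membrane calcium-transporting ATPase 3	FALSE	FALSE
Q15904	ATP6AP1	V-type proton ATPase subunit S1	FALSE	FALSE
O75787	ATP6AP2	Renin receptor	TRUE	TRUE
Q04656	ATP7A	Copper-transporting ATPase 1	TRUE	TRUE
P51572	BCAP31	B-cell receptor-associated protein 31	FALSE	FALSE
P21810	BGN	Biglycan	FALSE	FALSE
P32247	BRS3	Bombesin receptor subtype-3	TRUE	TRUE
O60840	CACNA1F	Voltage-dependent L-type calcium channel subunit alpha-1F	TRUE	TRUE
P51795	CLCN5	H(+)/Cl(−) exchange transporter 5	TRUE	TRUE
P57739	CLDN2	Claudin-2	TRUE	TRUE
Q9HC73	CRLF2	Cytokine receptor-like factor 2	FALSE	FALSE
Q5H943	CT83	Kita-kyushu lung cancer antigen 1	TRUE	FALSE
P04839	CYBB	Cytochrome b-245 heavy chain	TRUE	TRUE
P11532	DMD	Dystrophin	TRUE	FALSE
Q92838	EDA	Ectodysplasin-A	TRUE	TRUE
Q16206	ENOX2	Ecto-NOX disulfide-thiol exchanger 2	TRUE	TRUE
P34903	GABRA3	Gamma-aminobutyric acid receptor subunit alpha-3	FALSE	FALSE
Q9HCC8	GDPD2	Glycerophosphoinositol inositolphosphodiesterase GDPD2	TRUE	TRUE
P51654	GPC3	Glypican-3	TRUE	FALSE
O75487	GPC4	Glypican-4	TRUE	TRUE
Q14627	IL13RA2	Interleukin-13 receptor subunit alpha-2	TRUE	FALSE
Q9NZN1	IL1RAPL1	Interleukin-1 receptor accessory protein-like 1	TRUE	TRUE
P51617	IRAK1	Interleukin-1 receptor-associated kinase 1	FALSE	FALSE
P32004	L1CAM	Neural cell adhesion molecule L1	FALSE	FALSE
P13473	LAMP2	Lysosome-associated membrane glycoprotein 2	TRUE	FALSE
Q9H0U3	MAGT1	Magnesium transporter protein 1	TRUE	FALSE
Q8N4V1	MMGT1	ER membrane protein complex subunit 5	TRUE	TRUE
Q8NHP6	MOSPD2	Motile sperm domain-containing protein 2	TRUE	FALSE
P26038	MSN	Moesin	TRUE	TRUE
Q00604	NDP	Norrin	TRUE	TRUE
Q9Y5S8	NOX1	NADPH oxidase 1	TRUE	TRUE
O00264	PGRMC1	Membrane-associated progesterone receptor component 1	TRUE	FALSE
Q04941	PLP2	Proteolipid protein 2	TRUE	FALSE
Q96NR3	PTCHD1	Patched domain-containing protein 1	TRUE	TRUE
O95258	SLC25A14	Brain mitochondrial carrier protein 1	TRUE	FALSE
P05141	SLC25A5	ADP/ATP translocase 2	TRUE	FALSE
Q9UN76	SLC6A14	Sodium- and chloride-dependent neutral and basic amino acid transporter B(0+)	TRUE	FALSE
Q92581	SLC9A6	Sodium/hydrogen exchanger 6	TRUE	TRUE
Q9H156	SLITRK2	SLIT and NTRK-like protein 2	FALSE	FALSE
P78539	SRPX	Sushi repeat-containing protein SRPX	TRUE	FALSE
P08842	STS	Steryl-sulfatase	FALSE	FALSE
P08247	SYP	Synaptophysin	TRUE	FALSE
Q9UKZ4	TENM1	Teneurin-1	TRUE	TRUE
P41732	TSPAN7	Tetraspanin-7	TRUE	FALSE
P51809	VAMP7	Vesicle-associated membrane protein 7	FALSE	FALSE
Q86XK7	VSIG1	V-set and immunoglobulin domain-containing protein 1	TRUE	TRUE
P51811	XK	Endoplasmic reticulum membrane adapter protein XK	TRUE	TRUE
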