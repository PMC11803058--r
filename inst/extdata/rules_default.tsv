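rule_id	smarts	weight	superclass	subclass
aci01	c-[CX3](=O)[OX2H1]	10	organic acids and derivatives	benzoic acids and derivatives
aci02	[CX4]-[CX3](=O)[OX2H1]	9	organic acids and derivatives	carboxylic acids
aci03	[CX3](=O)[OX2H1]	8.5	organic acids and derivatives	carboxylic acids
aci04	[CX4][SX4](=O)(=O)[OX2H1]	8	organic acids and derivatives	sulfonic acids
alk01	c1ccc2c(c1)cccn2	8	alkaloids and derivatives	quinolines and derivatives
alk02	c1ccc2c(c1)ccnc2	8	alkaloids and derivatives	isoquinolines and derivatives
alk03	c1ncc2[nH]cnc2n1	9	alkaloids and derivatives	purines and derivatives
ben01	c1ccccc1	3	benzenoids	benzene and substituted derivatives
ben02	[OX2H]c1ccccc1	4	benzenoids	phenols
ben03	c1ccc2ccccc2c1	4	benzenoids	naphthalenes
dip01	[N-]=[N+]=N	9	organic 1,3-dipolar compounds	azides
dip02	[#6]=[N+]=[N-]	9	organic 1,3-dipolar compounds	diazo compounds
hal01	[F,Cl,Br,I]	2	organohalogen compounds	halogenated hydrocarbons
het01	c1ccncc1	8	organoheterocyclic compounds	pyridines and derivatives
het02	c1ccoc1	8	organoheterocyclic compounds	furans
het03	c1ccsc1	8	organoheterocyclic compounds	thiophenes
het04	c1cc[nH]c1	8	organoheterocyclic compounds	pyrroles
het05	c1cnc[nH]1	8.2	organoheterocyclic compounds	imidazoles
het06	c1ccncn1	8.1	organoheterocyclic compounds	pyrimidines
het07	c1ccc2c(c1)cc[nH]2	8.3	organoheterocyclic compounds	indoles
het08	[#7;R;!a]	4.5	organoheterocyclic compounds	saturated azacycles
het09	[#8;R;!a;!$([OX2R][CX3]=O)]	4.4	organoheterocyclic compounds	oxacycles
het10	[#16;R;!a]	4.3	organoheterocyclic compounds	thiacycles
het11	n	7	organoheterocyclic compounds	azaarenes
lig01	[OX2H]c1ccccc1OC	7	lignans, neolignans and related compounds	guaiacyl compounds
lig02	COc1cc(cc(OC)c1)C=C	7	lignans, neolignans and related compounds	neolignan skeletons
lip01	CCCCCCCCCCCC	5	lipids and lipid-like molecules	fatty acyls
lip02	OCC(O)CO	6	lipids and lipid-like molecules	glycerolipids
lip03	[CX4]1[CX4][CX4]2[CX4][CX4][CX4]3[CX4][CX4][CX4][CX4]3[CX4]2[CX4]1	6	lipids and lipid-like molecules	steroid-like polycycles
nit01	c-[NX3;H2,H1;!$(N[CX3]=O);!$(N[SX4](=O)=O)]	9	organic nitrogen compounds	anilines
nit02	[NX3;H2,H1;!$(N[CX3]=O);!$(N-a);!$(N[SX4](=O)=O);!$([NX3;R])]	4	organic nitrogen compounds	aliphatic amines
nit03	[NX3][CX3]=O	6	organic nitrogen compounds	amides
nit04	[NX1]#[CX2]	6	organic nitrogen compounds	nitriles
nit05	[$([NX3](=O)=O),$([NX3+](=O)[O-])]	6	organic nitrogen compounds	nitro compounds
oxy01	[#6][CX3](=O)[OX2H0][#6]	7	organic oxygen compounds	carboxylic acid esters
oxy02	[#6;!$([CX3]=O)][CX3](=O)[#6;!$([CX3]=O)]	6	organic oxygen compounds	ketones
oxy03	[CX3H1](=O)[#6]	6	organic oxygen compounds	aldehydes
oxy04	[OX2H][CX4]	3.5	organic oxygen compounds	alcohols
oxy05	[OD2]([#6])[#6]	2.5	organic oxygen compounds	ethers
pho01	[PX4]=O	8	organophosphorus compounds	phosphoryl compounds
pho02	[#15]	7	organophosphorus compounds	other organophosphorus compounds
php01	c1ccccc1C=CC(=O)	8	phenylpropanoids and polyketides	cinnamic acids and derivatives
php02	O=c1ccc2ccccc2o1	9	phenylpropanoids and polyketides	coumarins and derivatives
php03	O=c1cc(-c2ccccc2)oc2ccccc12	9	phenylpropanoids and polyketides	flavonoids
sul01	[SX4](=O)(=O)[NX3]	10	organosulfur compounds	sulfonamides
sul02	[SX4](=O)(=O)([#6])[#6]	7	organosulfur compounds	sulfones
sul03	[#16X3](=O)([#6])[#6]	6	organosulfur compounds	sulfoxides
sul04	[SX2H]	5	organosulfur compounds	thiols
sul05	[SX2]([#6])[#6]	4	organosulfur compounds	thioethers
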