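# plantbgc biosynthetic domain library (62 profiles: 57 Pfam-sourced, 5 custom).
# Reconstructed membership: accessions, class labels and signature flags are the
# package's own curation of enzyme families recurrently involved in plant
# specialized metabolism; revise freely -- this file is data, not code.
# cutoff: per-profile maximum i-E-value; empty means the global default (1e-5).
profile_id	name	enzyme_class	is_signature	source	cutoff
PF00067	p450	cytochrome P450	FALSE	pfam
PF01397	Terpene_synth	terpene synthase	TRUE	pfam
PF03936	Terpene_synth_C	terpene synthase	TRUE	pfam
PF13243	SQHop_cyclase_C	terpene synthase	TRUE	pfam
PF13249	SQHop_cyclase_N	terpene synthase	TRUE	pfam
PF00494	SQS_PSY	terpene synthase	TRUE	pfam
PF05834	Lycopene_cycl	terpene synthase	TRUE	pfam
PF00348	polyprenyl_synt	prenyltransferase	FALSE	pfam
PF01040	UbiA	prenyltransferase	FALSE	pfam
PF00201	UDPGT	glycosyltransferase	TRUE	pfam
PF00534	Glycos_transf_1	glycosyltransferase	TRUE	pfam
PF00535	Glycos_transf_2	glycosyltransferase	TRUE	pfam
PF03033	Glyco_transf_28	glycosyltransferase	TRUE	pfam
PF04101	Glyco_tran_28_C	glycosyltransferase	FALSE	pfam
PF00232	Glyco_hydro_1	glycoside hydrolase	FALSE	pfam
PF00195	Chal_sti_synt_N	polyketide synthase	TRUE	pfam
PF02797	Chal_sti_synt_C	polyketide synthase	TRUE	pfam
PF00109	ketoacyl-synt	ketoacyl synthase	FALSE	pfam
PF02801	Ketoacyl-synt_C	ketoacyl synthase	FALSE	pfam
PF02431	Chalcone	chalcone isomerase	FALSE	pfam
PF00107	ADH_zinc_N	alcohol dehydrogenase	FALSE	pfam
PF08240	ADH_N	alcohol dehydrogenase	FALSE	pfam
PF00106	adh_short	short-chain dehydrogenase	FALSE	pfam
PF08659	KR	short-chain dehydrogenase	FALSE	pfam
PF01370	Epimerase	epimerase	FALSE	pfam
PF01073	3Beta_HSD	steroid dehydrogenase	FALSE	pfam
PF00171	Aldedh	aldehyde dehydrogenase	FALSE	pfam
PF00248	Aldo_ket_red	aldo-keto reductase	FALSE	pfam
PF00724	Oxidored_FMN	ene-reductase	FALSE	pfam
PF05368	NmrA	isoflavone reductase	FALSE	pfam
PF03171	2OG-FeII_Oxy	dioxygenase	FALSE	pfam
PF14226	DIOX_N	dioxygenase	FALSE	pfam
PF00891	Methyltransf_2	methyltransferase	FALSE	pfam
PF01596	Methyltransf_3	methyltransferase	FALSE	pfam
PF08241	Methyltransf_11	methyltransferase	FALSE	pfam
PF08242	Methyltransf_12	methyltransferase	FALSE	pfam
PF13489	Methyltransf_23	methyltransferase	FALSE	pfam
PF13649	Methyltransf_25	methyltransferase	FALSE	pfam
PF13847	Methyltransf_31	methyltransferase	FALSE	pfam
PF02458	Transferase	BAHD acyltransferase	FALSE	pfam
PF00698	Acyl_transf_1	acyltransferase	FALSE	pfam
PF00450	Peptidase_S10	SCPL acyltransferase	FALSE	pfam
PF00135	COesterase	carboxylesterase	FALSE	pfam
PF00407	Bet_v_1	Bet v1	TRUE	pfam
PF03088	Str_synth	strictosidine synthase	TRUE	pfam
PF00282	Pyridoxal_deC	amino acid decarboxylase	TRUE	pfam
PF01593	Amino_oxidase	amine oxidase	FALSE	pfam
PF01179	Cu_amine_oxid	copper amine oxidase	FALSE	pfam
PF08031	BBE	berberine bridge enzyme	TRUE	pfam
PF01494	FAD_binding_3	FAD monooxygenase	FALSE	pfam
PF01565	FAD_binding_4	FAD oxidoreductase	FALSE	pfam
PF02913	FAD-oxidase_C	FAD oxidoreductase	FALSE	pfam
PF00743	FMO-like	flavin monooxygenase	FALSE	pfam
PF00155	Aminotran_1_2	aminotransferase	FALSE	pfam
PF00202	Aminotran_3	aminotransferase	FALSE	pfam
PF03018	Dirigent	dirigent protein	TRUE	pfam
PF00141	peroxidase	peroxidase	FALSE	pfam
CUSTOM001	Pictet_Spenglerase	Bet v1	TRUE	custom
CUSTOM002	OSC_plant	terpene synthase	TRUE	custom
CUSTOM003	AromPT	prenyltransferase	FALSE	custom
CUSTOM004	SCPL_acyl	SCPL acyltransferase	FALSE	custom
CUSTOM005	CelSy_like	cellulose synthase-like	TRUE	custom
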