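# Product classification rules: a cluster carrying a signature gene of
# enzyme_class is assigned product_class; >=2 distinct products add "Hybrid",
# zero matches yield "Putative".
enzyme_class	product_class
terpene synthase	Terpene
polyketide synthase	Polyketide
glycosyltransferase	Saccharide
cellulose synthase-like	Saccharide
Bet v1	Alkaloid
strictosidine synthase	Alkaloid
amino acid decarboxylase	Alkaloid
berberine bridge enzyme	Alkaloid
dirigent protein	Lignan
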