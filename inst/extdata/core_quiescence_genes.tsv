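gene_id	gene_name	localization
SPNCRNA.821	NA	NA
SPAC22H10.13	zym1	NA
SPAC3G9.11c	pdc201	NA
SPAC1F7.06	hsp3105	NA
SPAC869.09	NA	subtel1R
SPAC869.07c	mel1	subtel1R
SPAC869.06c	hry1	subtel1R
SPAC869.04	NA	subtel1R
SPAC869.03c	NA	subtel1R
SPBPB21E7.01c	eno102	subtel2L
SPBPB21E7.02c	NA	subtel2L
SPBPB21E7.10	NA	subtel2L
SPBPB21E7.11	NA	subtel2L
SPNCRNA.1364	NA	NA
SPNCRNA.1573	NA	NA
SPBC2G2.17c	NA	NA
SPNCRNA.577	NA	NA
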