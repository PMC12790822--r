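symbol	taxon	accession
PTEN	9606	P90001
PTEN	10090	P90002
PTEN	7955	P90003
SMAD4	9606	P90004
SMAD4	10090	P90005
SMAD4	7955	P90006
TP53	9606	P90007
TP53	10090	P90008
TP53	7955	P90009
CDKN1A	9606	P90010
CDKN1A	10090	P90011
CDKN1A	7955	P90012
BCL2	9606	P90013
BCL2	10090	P90014
BCL2	7955	P90015
VEGFA	9606	P90016
VEGFA	10090	P90017
VEGFA	7955	P90018
STAT3	9606	P90019
STAT3	10090	P90020
STAT3	7955	P90021
KRAS	9606	P90022
KRAS	10090	P90023
KRAS	7955	P90024
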