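motif_name	iupac
TGBOXATPIN2	AACGTG
GBOXLERBCS	MCACGTGGC
ABRELATERD1	ACGTG
RYREPEATLEGUMINGMLEG	CATGCAY
CACGTGMOTIF	CACGTG
MYBCORE	CNGTTR
WBOXNTERF3	TGACY
GT1CONSENSUS	GRWAAW
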