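>synthetic_chaperonin_query synthetic 543-residue group II chaperonin-like test sequence (not a natural protein); Cys at 140,237,286,359,393,470,484
PMLSDQPKPPHKRLSTASQSVKYDETGKIRMVSRMIYVKRVDSVEPMDLVFVMPGTEIGP
KTSAIKLTGRKYELPIHQVYVLLLSREGSLGDKEPPSKVDADRAGVPKEALRTGSFEIRG
IIDKSGVGYNKTFTTGVTECVTGEKYLGPPWNLVVFMEVKRFQAGQAPVTSSEADDYSQV
LINLGFGAMPTPLLKGAKMVLGDNTRANRGYIYMVLSTYEPGRLYGKTLSAAPLSGCSGI
GGSEMRHKKNKKFTESKKGDLAGLIIEDIITGKQAETQKGPPRSLCAYAMEFARKSIFDV
ENTGKRVIVVNGDTGFVLESGPRWVKALHDKVDSYEITAFKTVEIKERNVRSGLSGVKCT
AETVERRLVERRKGMMEPMEAFKIYVHEPAVKCREFTWHSFYKPLIPLHGKPLAPKIKRF
EGKVGTRQWGSMDMAETTSVGEGSVQGDMTLGQPVWPFVALNLEELVASCHIQKSELGEN
VSDCSKYQVRLIRYREVLKSDTLGVDDDEKGEESLESLLSSADTQKQAMRTDNYRTGILY
KER
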