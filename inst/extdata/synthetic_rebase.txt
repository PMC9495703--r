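<1>SynEcoRI
<2>SynEcoRI
<3>Escherichia coli RY13
<4>synthetic record
<5>GAATTC
<8>synthetic fixture, REBASE-like flat format

<1>SynEcoRV
<3>Escherichia coli J62
<5>GATATC

<1>SynBamHI
<3>Bacillus amyloliquefaciens H
<5>GGATCC

<1>SynBsuRI
<3>Bacillus subtilis X5
<5>GGCC

<1>SynHindIII
<3>Haemophilus influenzae Rd
<5>AAGCTT

<1>SynPstI
<3>Providencia stuartii 164
<5>CTGCAG

<1>SynSalI
<3>Streptomyces albus G
<5>GTCGAC

<1>SynXbaI
<3>Xanthomonas badrii
<5>TCTAGA

<1>SynKpnI
<3>Klebsiella pneumoniae OK8
<5>GGTACC

<1>SynSacI
<3>Streptomyces achromogenes
<5>GAGCT(1/5)C

<1>SynStyI
<3>Salmonella typhi 27
<5>CCWWGG

<1>SynDraII
<3>Deinococcus radiodurans
<5>RGGNCCY

<1>SynUnk
<3>Unidentified bacterium
<5>ACGCGT

<1>SynEcoAlt
<3>Escherichia coli B
<5>CCAGG
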