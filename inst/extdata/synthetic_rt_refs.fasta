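>lineageA_synthetic
LRRMTVWGGQRVFLGWQKTSGLPQGSWKEGSEFRIYSTEWGMKSGKWAISPLLFNLVMDELAMVSRRESMKEPYVPSVDP
FYVKTRVRYVDDWLVLAEEWRSYIGLMSFPVKELDIKARTEGLEINPTKTQVVAQEVRSPTEPTKGARIFEDGMLQFRPI
KVGGQVVERVVNSSMRTAIIVAEPMYGMDFLRQYADDVLLFAKSPEGLWEGDARSQLRTGLSRLMWKENLGVELDSWGNE
ARKVPLAYIVNGPADIQFYISQASAWMPVKRELFKRTVNWLFTERKQSVDEPKPSVVMDR
>lineageD_synthetic
FSPFISMSKYVGFLGWQKTSGLPQGSAADKQTQIKGPPLEFDDLRNKAISPLLFNLVMDELAAYMMENAEVQGVNDWQTY
GRSITRVRYVDDWLVLAEANLLTAQSPMEEETIQVDWLVWEGLEINPTKTQVVAVYTAYLWRMKDREFFTIGRASRFRPI
KVGGQVVERVDVAVNFRRWENAYKFMRGNRWTQYADDVLLFAKSPENTAYSPLIPVRYDPSSEEMGIYNLGVELDSWGNE
ARGYWDGTESEWAQSYLKTDIIMNAWMPVKRELFKRTVTVPYTNVTFRVIAFVLSWMRIN
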