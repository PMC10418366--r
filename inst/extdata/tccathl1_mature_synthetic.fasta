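>tccathl1_mature_synthetic | synthetic stand-in for mature T. castaneum cathepsin L | offset=115 | ionizables D14 E10 H2 K4 R5
AGRTKLIPFNQAGSTVLIPENQCGHDVLEPFNQAGSTVLIPFERAGSTDLDPFNQAGSTR
LIPFNQDGSTVLDPFDQAGSTVLIPFNQAGDTVKIPFNQAGDTVLRPFNQKEETVEIPFN
QAGDTVLIPDNQEGSAVLIPFNQAGSTVDIPFNQADETVHIVFNQAKSEDLIPFNQAGSN
VWIPFNQAGSTVLIPFNQAGSTVLIPFEQARSTVLIPFND
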