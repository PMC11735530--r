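>IGHV4-34*01
GAAGTTGGTCTTTCTCAATGGGATAAAGCTCGTTTTTATAATATTCATCAAGAAGTTGGTCTTTCTACTGCTGTTTATGC
TCGTTTTTATAATATTCATCAAGAAGTTGGTCTTTCTACTCCTGATAAAGCTCGTTTTTATAATATTCATCAAGAAGTTG
GTCTTTCTAATCATTCTAAAGCTCGTTTTTATAATATTCATCAAGAAGTTGGTCTTTCTACTCCTGATAAAGCTCGTTTT
TATAATATTCATCAAGAAGTTGGTCTTAAACTTTCTGATAAAGCTCGTTTTTAT
>IGHV1-2*01
CTTTCTACTCCTGATAAAGCTCGTTTTTATAATATTCATCAAGAAGTTGGTCTTTCTACTCCTGATAAAGCTCGTTTTTA
TAATATTCATCAAGAAGTTGGTCTTTCTACTCCTGATAAAGCTCGTTTTTATAATATTCATCAAGAAGTTGGTCTTTCTA
CTCCTGATAAAGCTCGTTTTTATAATATTCATCAAGAAGTTGGTCTTTCTACTCCTGATAAAGCTCGTTTTTATAATATT
CATCAAGAAGTTGGTCTTTCTACTCCTGATAAAGCTCGTTTTTATAATATTCAT
>IGHV1-69*01
CCTGATAAAGCTCGTTTTTATAATATTCATCAAGAAGTTGGTCTTTCTACTCCTGATAAAGCTCGTTTTTATAATATTCA
TCAAGAAGTTGGTCTTTCTACTCCTGATAAAGCTCGTTTTTATAATATTCATCAAGAAGTTGGTCTTTCTACTCCTGATA
AAGCTCGTTTTTATAATATTCATCAAGAAGTTGGTCTTTCTACTCCTGATAAAGCTCGTTTTTATAATATTCATCAAGAA
GTTGGTCTTTCTACTCCTGATAAAGCTCGTTTTTATAATATTCATCAAGAAGTT
>IGHV3-23*01
GCTCGTTTTTATAATATTCATCAAGAAGTTGGTCTTTCTACTCCTGATAAAGCTCGTTTTTATAATATTCATCAAGAAGT
TGGTCTTTCTACTCCTGATAAAGCTCGTTTTTATAATATTCATCAAGAAGTTGGTCTTTCTACTCCTGATAAAGCTCGTT
TTTATAATATTCATCAAGAAGTTGGTCTTTCTACTCCTGATAAAGCTCGTTTTTATAATATTCATCAAGAAGTTGGTCTT
TCTACTCCTGATAAAGCTCGTTTTTATAATATTCATCAAGAAGTTGGTCTTTCT
>IGHV3-30*01
TATAATATTCATCAAGAAGTTGGTCTTTCTACTCCTGATAAAGCTCGTTTTTATAATATTCATCAAGAAGTTGGTCTTTC
TACTCCTGATAAAGCTCGTTTTTATAATATTCATCAAGAAGTTGGTCTTTCTACTCCTGATAAAGCTCGTTTTTATAATA
TTCATCAAGAAGTTGGTCTTTCTACTCCTGATAAAGCTCGTTTTTATAATATTCATCAAGAAGTTGGTCTTTCTACTCCT
GATAAAGCTCGTTTTTATAATATTCATCAAGAAGTTGGTCTTTCTACTCCTGAT
>IGHV4-39*01
CATCAAGAAGTTGGTCTTTCTACTCCTGATAAAGCTCGTTTTTATAATATTCATCAAGAAGTTGGTCTTTCTACTCCTGA
TAAAGCTCGTTTTTATAATATTCATCAAGAAGTTGGTCTTTCTACTCCTGATAAAGCTCGTTTTTATAATATTCATCAAG
AAGTTGGTCTTTCTACTCCTGATAAAGCTCGTTTTTATAATATTCATCAAGAAGTTGGTCTTTCTACTCCTGATAAAGCT
CGTTTTTATAATATTCATCAAGAAGTTGGTCTTTCTACTCCTGATAAAGCTCGT
>IGHV5-51*01
GTTGGTCTTTCTACTCCTGATAAAGCTCGTTTTTATAATATTCATCAAGAAGTTGGTCTTTCTACTCCTGATAAAGCTCG
TTTTTATAATATTCATCAAGAAGTTGGTCTTTCTACTCCTGATAAAGCTCGTTTTTATAATATTCATCAAGAAGTTGGTC
TTTCTACTCCTGATAAAGCTCGTTTTTATAATATTCATCAAGAAGTTGGTCTTTCTACTCCTGATAAAGCTCGTTTTTAT
AATATTCATCAAGAAGTTGGTCTTTCTACTCCTGATAAAGCTCGTTTTTATAAT
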