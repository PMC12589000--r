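epitope_class	sequence
HTL	LLQVVYLHSNNITKV
HTL	TTLLDLQNNDISELR
HTL	KISKIHEKAFSPLRK
HTL	RDGFKGEKGECLRES
HTL	GRDGFKGEKGECLRE
HTL	MNSTINIHRTSSVEG
HTL	FVSSMGSGNPAPGGV
HTL	GFVSSMGSGNPAPGG
HTL	VSSMGSGNPAPGGVC
HTL	IQKIIGEKYHALNSR
HTL	KPAEFTQHKFVKICM
HTL	RWKLLFDEIAKYNRG
HTL	NCPYVHNPAQIDTDN
HTL	DNCPYISNANQADHD
HTL	TAQLKQDGKSRGTLL
HTL	SEKFDLMAKLKQQKY
HTL	FDLMAKLKQQKYEIN
HTL	QQRFRTEKERERQAK
LBL	DEEASGADTSGVLDPD
LBL	ACCQRWYFTFNGAECS
LBL	PQSCVVDQTGSAHCVV
LBL	IGRPRWKLLFDEIAKY
LBL	SGTQQRGRSCDVTSNT
LBL	YNRISHAQKFRKGAGK
CTL	DPDSVTPTY
CTL	KLQKLYISK
CTL	KQKAQLRQR
CTL	IPKGKQKAQL
CTL	MRPGAPGPLW
CTL	VMYRGRCRK
CTL	SPFEESLNY
CTL	QANFPQTWLW
CTL	SVDFSGTFY
CTL	RVSNDNQFLW
CTL	MSDTEEQEY
CTL	KEEEELVAL
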