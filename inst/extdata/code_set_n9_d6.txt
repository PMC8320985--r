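# DNA storage code set: n = 9, d = 6, GC weight 4, no-runlength.
# 26 codewords, one per line.
ATCTGCTCA
ATCGAGATG
GTAGTCGAT
TATCGTAGC
TAGCTAGCT
TGTCAGCTA
GACTATCGA
AGTACGTAC
ACACAGTCT
CATATGACG
GATGTACTC
GATCACTAG
TAGACTCTG
TCGTCATGA
AGAGCAGTA
ATGATGCGA
CTATGACGT
AGATACAGC
TCACTCATG
TGCATCTGT
TCTAGAGAG
GTATCTACG
CACGCATAT
TCAGATCAC
CTGTATGTC
CGCAGTATA
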