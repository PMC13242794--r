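>SynPE/1
TTGAACCTAGGATCGTACAGCTTCGAATGCCTGA
>SynPE/2
ACCTAGCTTGCAACTGGTACGATCAGTCCGAACT
>SynSimple1
AGTTCGGACTGATCGTACCAGTTGCAAGCTAGGT
>SynSimple2
TCAGGCATTCGAAGCTGTACGATCCTAGGTTCAA
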