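position,exon_number,ref,alt,region,type,aa_change,sift
11031,2,G,A,exon,non-synonymous,p.S9N,neutral
11470,4,C,G,exon,non-synonymous,p.P80R,neutral
12379,5,C,-,exon,frameshift_deletion,p.N131fs,NA
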