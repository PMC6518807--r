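gene,allele,n_subjects
EGFR,L858R,33
EGFR,exon19del,25
KRAS,A146V,2
KRAS,A146X,1
KRAS,G12A,1
KRAS,G12C,3
KRAS,G12D,2
KRAS,G12V,6
KRAS,G13D,1
KRAS,Q61L,1
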