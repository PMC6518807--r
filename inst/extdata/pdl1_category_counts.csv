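histology,compartment,category,count
ADC,tc,negative,86
ADC,tc,weak,13
ADC,tc,moderate,10
ADC,tc,strong,27
ADC,ic,negative,88
ADC,ic,weak,14
ADC,ic,moderate,7
ADC,ic,strong,27
SQCC,tc,negative,23
SQCC,tc,weak,7
SQCC,tc,moderate,7
SQCC,tc,strong,14
SQCC,ic,negative,22
SQCC,ic,weak,15
SQCC,ic,moderate,2
SQCC,ic,strong,12
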