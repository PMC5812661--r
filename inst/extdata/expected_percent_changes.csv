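parameter,day,group,direction,expected
T1,1,cPH,increase,18
T1,1,ePH,increase,40
T1,2,cPH,increase,24
T1,2,ePH,increase,49
T2,5,cPH,increase,21
T2,5,ePH,increase,41
ADC,1,cPH,decrease,13
MTR,1,cPH,decrease,11
MTR,1,ePH,decrease,15
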