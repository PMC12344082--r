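system,T_K,P_MPa,rho_kg_m3,y2,y3,sd
ethanol-1%,308,12,768.4,7.660e-05,0.01,2.600e-06
ethanol-1%,308,15,816.1,7.680e-05,0.01,2.700e-06
ethanol-1%,308,18,848.9,9.500e-05,0.01,3.200e-06
ethanol-1%,308,21,874.4,1.038e-04,0.01,3.500e-06
ethanol-1%,308,24,895.5,1.216e-04,0.01,4.100e-06
ethanol-1%,308,27,913.7,1.377e-04,0.01,4.700e-06
ethanol-1%,308,30,929.7,1.423e-04,0.01,4.800e-06
ethanol-1%,318,12,659.7,7.010e-05,0.01,2.400e-06
ethanol-1%,318,15,743.2,1.065e-04,0.01,3.600e-06
ethanol-1%,318,18,790.2,1.318e-04,0.01,4.500e-06
ethanol-1%,318,21,823.7,1.578e-04,0.01,5.300e-06
ethanol-1%,318,24,850.1,1.687e-04,0.01,5.700e-06
ethanol-1%,318,27,872,1.815e-04,0.01,6.100e-06
ethanol-1%,318,30,890.9,2.031e-04,0.01,6.900e-06
ethanol-1%,328,12,506.9,6.220e-05,0.01,2.100e-06
ethanol-1%,328,15,654.9,9.140e-05,0.01,3.100e-06
ethanol-1%,328,18,724.1,1.536e-04,0.01,5.200e-06
ethanol-1%,328,21,768.7,2.026e-04,0.01,6.900e-06
ethanol-1%,328,24,801.9,2.237e-04,0.01,7.600e-06
ethanol-1%,328,27,828.5,2.434e-04,0.01,8.200e-06
ethanol-1%,328,30,850.8,2.558e-04,0.01,8.700e-06
ethanol-1%,338,12,384.2,4.050e-05,0.01,1.300e-06
ethanol-1%,338,15,555.2,9.250e-05,0.01,3.100e-06
ethanol-1%,338,18,651.2,1.808e-04,0.01,6.100e-06
ethanol-1%,338,21,709.7,2.204e-04,0.01,7.500e-06
ethanol-1%,338,24,751.2,2.502e-04,0.01,8.500e-06
ethanol-1%,338,27,783.3,2.858e-04,0.01,9.700e-06
ethanol-1%,338,30,809.6,3.143e-04,0.01,1.070e-05
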