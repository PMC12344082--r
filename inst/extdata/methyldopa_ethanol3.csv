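system,T_K,P_MPa,rho_kg_m3,y2,y3,sd
ethanol-3%,308,12,768.4,2.259e-04,0.03,7.000e-07
ethanol-3%,308,15,816.1,2.456e-04,0.03,9.000e-07
ethanol-3%,308,18,848.9,2.759e-04,0.03,1.000e-06
ethanol-3%,308,21,874.4,2.964e-04,0.03,1.000e-06
ethanol-3%,308,24,895.5,3.405e-04,0.03,1.300e-06
ethanol-3%,308,27,913.7,3.793e-04,0.03,1.100e-06
ethanol-3%,308,30,929.7,4.677e-04,0.03,1.200e-06
ethanol-3%,318,12,659.7,2.001e-04,0.03,7.000e-07
ethanol-3%,318,15,743.2,3.044e-04,0.03,8.000e-07
ethanol-3%,318,18,790.2,3.766e-04,0.03,1.000e-06
ethanol-3%,318,21,823.7,4.510e-04,0.03,1.100e-06
ethanol-3%,318,24,850.1,4.819e-04,0.03,1.200e-06
ethanol-3%,318,27,872,5.187e-04,0.03,1.600e-06
ethanol-3%,318,30,890.9,5.803e-04,0.03,1.900e-06
ethanol-3%,328,12,506.9,1.872e-04,0.03,5.000e-07
ethanol-3%,328,15,654.9,3.097e-04,0.03,8.000e-07
ethanol-3%,328,18,724.1,4.387e-04,0.03,1.100e-06
ethanol-3%,328,21,768.7,5.789e-04,0.03,1.400e-06
ethanol-3%,328,24,801.9,6.392e-04,0.03,1.500e-06
ethanol-3%,328,27,828.5,6.953e-04,0.03,1.700e-06
ethanol-3%,328,30,850.8,7.361e-04,0.03,1.900e-06
ethanol-3%,338,12,384.2,1.225e-04,0.03,3.000e-07
ethanol-3%,338,15,555.2,2.660e-04,0.03,9.000e-07
ethanol-3%,338,18,651.2,5.165e-04,0.03,1.400e-06
ethanol-3%,338,21,709.7,6.298e-04,0.03,1.600e-06
ethanol-3%,338,24,751.2,7.149e-04,0.03,1.900e-06
ethanol-3%,338,27,783.3,8.166e-04,0.03,2.100e-06
ethanol-3%,338,30,809.6,8.979e-04,0.03,2.300e-06
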