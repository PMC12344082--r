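system,T_K,P_MPa,rho_kg_m3,y2,y3,sd
binary,308,12,768.4,2.380e-05,0,9.000e-07
binary,308,15,816.1,2.900e-05,0,1.100e-06
binary,308,18,848.9,3.850e-05,0,1.500e-06
binary,308,21,874.4,4.340e-05,0,1.700e-06
binary,308,24,895.5,5.290e-05,0,2.100e-06
binary,308,27,913.7,6.240e-05,0,2.500e-06
binary,308,30,929.7,7.950e-05,0,3.200e-06
binary,318,12,659.7,1.790e-05,0,7.000e-07
binary,318,15,743.2,3.230e-05,0,1.300e-06
binary,318,18,790.2,4.390e-05,0,1.700e-06
binary,318,21,823.7,5.770e-05,0,2.300e-06
binary,318,24,850.1,6.970e-05,0,2.800e-06
binary,318,27,872,7.590e-05,0,3.000e-06
binary,318,30,890.9,8.630e-05,0,3.400e-06
binary,328,12,506.9,1.480e-05,0,6.000e-07
binary,328,15,654.9,2.730e-05,0,1.100e-06
binary,328,18,724.1,4.840e-05,0,1.900e-06
binary,328,21,768.7,6.880e-05,0,2.700e-06
binary,328,24,801.9,7.780e-05,0,3.100e-06
binary,328,27,828.5,8.960e-05,0,3.600e-06
binary,328,30,850.8,9.750e-05,0,3.900e-06
binary,338,12,384.2,7.800e-06,0,3.000e-07
binary,338,15,555.2,1.970e-05,0,8.000e-07
binary,338,18,651.2,5.230e-05,0,2.100e-06
binary,338,21,709.7,7.240e-05,0,2.900e-06
binary,338,24,751.2,8.450e-05,0,3.400e-06
binary,338,27,783.3,9.810e-05,0,3.900e-06
binary,338,30,809.6,1.082e-04,0,4.300e-06
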