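duration,session,scenario,lag_ms,jitter_ms
15min,1,I,32.69,0.07
15min,2,I,32.76,0.09
15min,3,I,32.81,0.07
15min,4,I,32.68,0.09
15min,5,I,32.67,0.07
15min,1,II,-1.56,3.06
15min,2,II,-53.07,3.91
15min,3,II,-10.5,3.02
15min,4,II,-1.98,2.05
15min,5,II,-21.67,1.84
15min,1,III,29.75,1.22
15min,2,III,24.92,1.5
15min,3,III,37.98,1.49
15min,4,III,29.8,1.41
15min,5,III,15.36,1.24
3h,1,I,32.64,0.09
3h,2,I,32.65,0.09
3h,1,II,-13.2,3.82
3h,2,II,-7.89,2.84
3h,1,III,25.19,3.33
3h,2,III,24.61,2.99
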