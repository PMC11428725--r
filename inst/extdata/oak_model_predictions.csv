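run,temperature,ethanol,time,dpph_ffd,dpph_ann,frap_ffd,frap_ann,tpc_ffd,tpc_ann
1,20,0,3,49.58,80.03,108.73,124.03,72.63,107.60
2,20,0,6,50.13,90.91,109.88,154.68,74.71,100.55
3,20,0,24,53.43,50.56,116.78,173.86,87.21,70.00
4,20,20,3,142.21,93.88,214.00,144.68,97.47,130.31
5,20,20,6,139.36,119.72,215.54,207.41,99.38,123.91
6,20,20,24,122.25,117.40,224.81,217.71,110.84,137.75
7,20,40,3,234.83,236.11,319.27,274.15,122.32,158.90
8,20,40,6,228.58,319.80,321.21,429.46,124.05,158.94
9,20,40,24,191.06,205.53,332.83,313.00,134.47,180.55
10,50,0,3,150.35,121.93,256.11,186.74,157.61,110.35
11,50,0,6,148.75,165.07,249.31,249.51,159.39,111.00
12,50,0,24,139.18,116.96,208.48,202.20,170.11,131.99
13,50,20,3,215.70,141.92,313.63,225.96,181.43,120.49
14,50,20,6,215.64,168.19,315.01,255.13,184.14,131.82
15,50,20,24,215.27,218.12,323.27,273.73,200.37,146.86
16,50,40,3,281.06,311.50,371.15,364.13,205.25,155.19
17,50,40,6,282.53,326.93,380.71,393.38,208.88,165.17
18,50,40,24,291.37,341.79,438.07,485.69,230.63,233.86
19,80,0,3,251.12,314.86,403.49,494.92,242.59,241.04
20,80,0,6,247.38,231.34,388.73,344.60,244.08,233.94
21,80,0,24,224.92,212.08,300.18,315.31,253.01,249.10
22,80,20,3,289.20,258.35,413.26,381.11,265.39,338.50
23,80,20,6,291.93,249.25,414.48,341.47,268.89,364.56
24,80,20,24,308.30,315.08,421.74,445.88,289.91,358.56
25,80,40,3,327.28,368.56,423.04,489.75,288.18,282.63
26,80,40,6,336.48,337.29,440.22,435.94,293.70,290.92
27,80,40,24,391.67,359.10,543.31,526.07,338.99,340.89
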