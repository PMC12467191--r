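group,cause,measure,year,value,lower,upper
Global,Neoplasms,deaths,1990,148.24,140.18,154.39
Global,Neoplasms,dalys,1990,3969.21,3792.05,4135.06
Global,Neoplasms,deaths,2021,116.49,107.28,124.69
Global,Neoplasms,dalys,2021,2953.59,2769.24,3154.03
High SDI,Neoplasms,deaths,1990,170.96,162.88,175.00
High SDI,Neoplasms,dalys,1990,4341.14,4215.00,4430.83
High SDI,Neoplasms,deaths,2021,123.22,113.06,128.96
High SDI,Neoplasms,dalys,2021,2920.60,2751.48,3031.34
High-middle SDI,Neoplasms,deaths,1990,173.65,163.76,182.46
High-middle SDI,Neoplasms,dalys,1990,4809.50,4539.00,5055.08
High-middle SDI,Neoplasms,deaths,2021,134.01,121.72,147.09
High-middle SDI,Neoplasms,dalys,2021,3388.27,3078.37,3728.81
Middle SDI,Neoplasms,deaths,1990,135.62,125.17,146.36
Middle SDI,Neoplasms,dalys,1990,3778.75,3482.10,4077.32
Middle SDI,Neoplasms,deaths,2021,109.59,99.35,121.22
Middle SDI,Neoplasms,dalys,2021,2852.23,2611.28,3158.67
Low-middle SDI,Neoplasms,deaths,1990,82.45,75.29,88.04
Low-middle SDI,Neoplasms,dalys,1990,2408.70,2227.63,2562.93
Low-middle SDI,Neoplasms,deaths,2021,85.03,79.17,90.89
Low-middle SDI,Neoplasms,dalys,2021,2376.66,2202.92,2542.90
Low SDI,Neoplasms,deaths,1990,98.74,87.84,110.68
Low SDI,Neoplasms,dalys,1990,2864.53,2554.22,3184.28
Low SDI,Neoplasms,deaths,2021,90.64,79.86,102.00
Low SDI,Neoplasms,dalys,2021,2487.39,2164.52,2827.72
Global,COPD,deaths,1990,71.92,64.47,77.53
Global,COPD,dalys,1990,1492.64,1342.46,1609.30
Global,COPD,deaths,2021,45.22,40.61,49.70
Global,COPD,dalys,2021,940.66,871.48,1014.59
High SDI,COPD,deaths,1990,25.53,23.71,26.50
High SDI,COPD,dalys,1990,589.80,557.84,616.39
High SDI,COPD,deaths,2021,19.44,17.26,20.66
High SDI,COPD,dalys,2021,471.22,437.45,498.84
High-middle SDI,COPD,deaths,1990,79.53,70.61,86.61
High-middle SDI,COPD,dalys,1990,1511.32,1365.74,1635.67
High-middle SDI,COPD,deaths,2021,35.91,30.78,40.69
High-middle SDI,COPD,dalys,2021,691.14,621.83,772.74
Middle SDI,COPD,deaths,1990,123.89,109.19,134.80
Middle SDI,COPD,dalys,1990,2332.91,2063.49,2546.31
Middle SDI,COPD,deaths,2021,57.45,49.59,65.43
Middle SDI,COPD,dalys,2021,1076.67,963.62,1201.24
Low-middle SDI,COPD,deaths,1990,92.07,74.17,107.46
Low-middle SDI,COPD,dalys,1990,1963.19,1602.24,2252.75
Low-middle SDI,COPD,deaths,2021,84.76,75.80,93.78
Low-middle SDI,COPD,dalys,2021,1707.90,1558.88,1865.11
Low SDI,COPD,deaths,1990,77.67,61.91,91.44
Low SDI,COPD,dalys,1990,1673.81,1373.37,1936.99
Low SDI,COPD,deaths,2021,70.70,63.35,79.76
Low SDI,COPD,dalys,2021,1457.94,1318.76,1617.05
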