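analysis,d18O_vpdb,d18O_vsmow,error_2sd,d18O_raw,date,relative_yield,dist_um,pit_category,clfm_greyscale
2-9,-1.7,29.2,0.3,27.1,,97.60,8.1,1,0.40
2-6,-1.0,29.9,0.3,27.8,,95.00,49.4,1,2.81
2-5,-1.7,29.2,0.3,27.2,,95.70,54.2,2,-0.81
3-12,-1.4,29.5,0.4,27.4,,96.60,60.5,1,-4.19
3-10,-0.8,30.1,0.4,28.0,,96.30,65.3,1,-4.52
2-4,-0.8,30.1,0.3,28.1,,95.30,66.1,1,-4.31
3-9,-0.8,30.1,0.4,28.0,,95.80,69.2,1,-0.20
3-8,-0.7,30.2,0.4,28.1,,96.10,78.8,1,9.39
3-7,-1.0,29.9,0.4,27.8,,95.50,87.5,2,-6.69
3-6,-0.9,30.0,0.3,27.9,,96.70,99.4,1,0.98
3-5,-0.8,30.1,0.3,28.0,,95.60,107.3,1,-2.84
3-13,-1.6,29.3,0.4,27.2,,96.20,108.1,1,-1.81
1-10,-1.1,29.8,0.4,27.8,,96.60,116.9,1,1.12
1-9,-1.6,29.3,0.4,27.3,,97.80,125.6,1,-3.90
3-3,-1.4,29.5,0.3,27.4,,96.20,132.7,1,1.13
1-8,-1.4,29.5,0.4,27.5,,97.80,134.3,1,0.75
3-2,-1.5,29.3,0.3,27.2,,95.70,139.9,1,2.48
1-7,-1.5,29.4,0.4,27.4,,97.50,143.0,1,8.08
3-1,-1.8,29.1,0.3,27.0,,95.90,148.6,1,-7.16
1-4,-1.8,29.1,0.4,27.1,,96.90,174.0,1,0.84
1-3,-1.8,29.1,0.4,27.1,,97.30,189.9,2,-1.39
4-14,-1.9,29.0,0.2,27.1,,98.30,208.9,1,-3.36
4-8,-1.9,29.0,0.3,27.1,,98.10,216.9,1,0.66
4-18,-1.1,29.8,0.2,27.9,,95.40,228.8,1,1.66
4-7,-2.2,28.7,0.3,26.8,,98.70,232.7,1,0.06
4-12,-1.6,29.3,0.2,27.4,,97.00,236.7,2,-2.80
4-5,-1.5,29.4,0.3,27.5,,97.60,258.9,2,-6.19
4-3,-1.4,29.5,0.3,27.6,,97.80,280.3,1,-0.98
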