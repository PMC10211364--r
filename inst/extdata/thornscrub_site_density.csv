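species,site,n_ha,g_ha,ivi
A. amentacea,10,70.31,0.20,15.73
A. amentacea,>30,215.63,0.49,8.17
A. farnesiana,10,1415.63,1.97,76.16
A. farnesiana,20,931.25,5.88,60.56
A. farnesiana,30,459.38,6.02,49.49
A. farnesiana,>30,156.25,0.53,7.24
A. rigidula,30,7.81,0.05,1.64
B. myricifolia,>30,1.56,0.005,0.64
C. boissieri,20,20.31,0.19,4.66
C. boissieri,30,4.69,0.02,2.53
C. boissieri,>30,185.94,1.77,12.45
C. erecta,30,26.56,0.13,5.03
C. erecta,>30,4.69,0.01,0.72
C. hookeri,>30,51.56,0.38,4.76
C. mexicana,20,23.44,0.13,2.87
C. pallida,20,29.69,0.04,2.62
C. pallida,30,17.19,0.06,5.45
C. pallida,>30,28.13,0.09,2.06
D. texana,30,45.31,0.14,5.90
D. texana,>30,429.69,2.34,19.01
E. ebano,20,4.69,0.07,2.03
E. ebano,>30,31.25,0.08,1.47
E. polystachya,>30,54.69,0.19,4.08
F. angustifolia,20,15.63,0.02,2.13
F. angustifolia,>30,4.69,0.03,0.78
G. angustifolium,20,1.56,0.00,1.64
G. angustifolium,>30,6.25,0.02,1.99
H. pallens,10,9.38,0.02,4.16
H. pallens,20,28.13,0.13,4.58
H. pallens,>30,434.38,1.30,15.18
H. parvifolia,20,3.13,0.01,1.71
H. parvifolia,>30,31.25,0.11,2.77
K. spinosa,30,9.38,0.02,1.60
L. frutescens,>30,1.56,0.01,0.65
M. monancistra,20,1.56,0.00,1.64
P. aculeata,30,20.31,0.18,2.74
P. laevigata,20,85.94,0.67,11.95
P. laevigata,30,90.63,0.99,12.53
P. laevigata,>30,20.31,0.07,1.21
P. texana,30,31.25,0.24,4.59
P. texana,>30,31.25,0.18,3.05
R. obcordata,20,4.69,0.00,1.73
R. obcordata,>30,3.13,0.01,0.68
S. celastrinum,20,7.81,0.02,1.88
S. celastrinum,30,28.13,0.09,3.83
S. celastrinum,>30,78.13,0.51,5.72
Y. filifera,>30,4.69,0.55,3.35
Z. fagara,10,4.69,0.01,3.95
Z. fagara,30,21.88,0.09,4.66
Z. fagara,>30,53.13,0.18,4.04
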