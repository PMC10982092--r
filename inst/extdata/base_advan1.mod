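$PROBLEM One-compartment iv bolus base model
$INPUT ID TIME EVID AMT DV MDV SEX AGE BMI CR HT WT BSA CRCL
$DATA data.csv IGNORE=#
$SUBROUTINES ADVAN1 TRANS2
$PK
{{PK_BLOCK}}
$ERROR
IPRED = F
Y = IPRED*(1+EPS(1)) + EPS(2)
$THETA
{{THETA_BLOCK}}
$OMEGA BLOCK(2)
0.1
0.01 0.1
$SIGMA
0.01
0.01
$ESTIMATION METHOD=0 MAXEVAL=9999 PRINT=5 POSTHOC
$COVARIANCE
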