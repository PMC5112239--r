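subject,pain_detect_current,pain_detect_ave4w,pain_detect_total,rmd,ppt
P01,3,4.3,3,2,75
P02,2,4.3,5,4,40
P03,0,3.3,2,4,60
P04,3,5.3,8,11,65
P05,1,2.7,3,1,57
P06,3,4.3,5,5,55
P07,2,4.3,5,2,25
P08,3,3.7,1,3,45
P09,0,3.7,14,6,20
P10,2,4.0,11,1,20
P11,2,4.3,7,1,40
P12,2,3.3,6,4,32
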