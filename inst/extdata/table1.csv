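subject,cohort,age,sex,location,size,ruptured,followup_months
01,recurrence,72,F,L paraophthalmic,26x17,Unruptured,10.5
02,recurrence,58,F,L MCA,16x11,Unruptured,5.8
03,recurrence,51,F,L vertebral,14x11,Unruptured,6.7
04,recurrence,50,M,Acom,4x13,Unruptured,18.6
05,recurrence,53,F,Acom,10x8,Unruptured,24.3
06,recurrence,60,F,R pcom,9x8,Unruptured,16.8
07,recurrence,46,F,L cavernous ICA,7x8,Unruptured,6.6
08,recurrence,49,F,Basilar tip,6x6,Unruptured,5.9
09,recurrence,47,M,Basilar tip,22x15,Ruptured,5.3
10,recurrence,59,F,R pcom,16x11,Ruptured,11.5
11,recurrence,22,M,R MCA terminus,7x10,Ruptured,4.3
12,recurrence,58,M,Acom,5x10,Ruptured,5.7
13,recurrence,68,F,Acom,9x8,Ruptured,12.1
14,recurrence,61,F,Basilar tip,6x6,Ruptured,2.0
15,recurrence,52,F,Acom,4x4,Ruptured,5.8
16,control,37,F,L ophthalmic,9x9,Unruptured,5.4
17,control,50,F,L paraophthalmic,9x8,Unruptured,5.5
18,control,50,F,L cavernous ICA,8x8,Unruptured,5.5
19,control,69,F,R ICA,7x7,Unruptured,19.7
20,control,40,F,R paraophthalmic,7x7,Unruptured,6.5
21,control,16,F,R cavernous ICA,5x3,Unruptured,6.4
22,control,47,F,R ICA terminus,4x4,Unruptured,22.6
23,control,69,F,R ICA,2x3,Unruptured,19.7
24,control,65,F,R pcom,8x3,Ruptured,8.2
25,control,61,F,R pcom,6x5,Ruptured,6.3
26,control,45,F,Basilar tip,5x4,Ruptured,14.7
27,control,45,F,Acom,3x5,Ruptured,6.7
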