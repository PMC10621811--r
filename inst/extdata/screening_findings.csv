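child,age,hvfqi_score,screen_trigger,findings_present,checklist_met
1,12,30,time_95th,TRUE,3
2,6,26,time_85th_accuracy_2,TRUE,2
3,5,26,time_95th,TRUE,2
4,10,24,time_95th,TRUE,3
5,8,21,time_95th,TRUE,2
6,7,21,accuracy_1,TRUE,2
7,7,15,accuracy_1,TRUE,2
8,7,8,accuracy_1,TRUE,1
9,8,6,accuracy_2,TRUE,3
10,5,5,time_85th,TRUE,1
11,5,4,time_85th,TRUE,1
12,10,17,time_95th,TRUE,3
13,6,12,time_85th,TRUE,1
14,5,10,time_85th,TRUE,1
15,12,8,accuracy_2,TRUE,1
16,7,2,accuracy_2,TRUE,1
17,6,NA,accuracy_0,TRUE,3
18,7,15,time_85th,FALSE,NA
19,8,12,time_95th,FALSE,NA
20,8,11,time_95th,FALSE,NA
21,5,8,time_85th,FALSE,NA
22,7,7,time_85th,FALSE,NA
23,6,2,time_95th,FALSE,NA
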