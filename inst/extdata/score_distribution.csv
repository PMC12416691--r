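dataset,lesion,score,count,percent
Training,fibers,0.0,1568,7.8
Training,fibers,0.5,2365,11.8
Training,fibers,1.0,16068,80.3
Training,specks,0.0,3333,17.8
Training,specks,0.5,647,3.5
Training,specks,1.0,14698,78.7
Training,mass,0.0,802,5.0
Training,mass,0.5,3175,19.9
Training,mass,1.0,12008,75.1
Test,fibers,0.0,261,7.8
Test,fibers,0.5,394,11.8
Test,fibers,1.0,2678,80.3
Test,specks,0.0,556,17.9
Test,specks,0.5,108,3.5
Test,specks,1.0,2450,78.7
Test,mass,0.0,134,5.0
Test,mass,0.5,529,19.9
Test,mass,1.0,2001,75.1
Evaluation,fibers,0.0,491,8.4
Evaluation,fibers,0.5,652,11.1
Evaluation,fibers,1.0,4735,80.6
Evaluation,specks,0.0,957,17.6
Evaluation,specks,0.5,205,3.8
Evaluation,specks,1.0,4271,78.6
Evaluation,mass,0.0,218,4.7
Evaluation,mass,0.5,941,20.3
Evaluation,mass,1.0,3487,75.1
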