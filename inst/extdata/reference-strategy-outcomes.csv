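strategy,threshold_pct,cases,overdiagnosed,pc_deaths,qalys,costs_millions,icer_vs_none,cumulative_percent_screened
no screening,NA,537870,0,192623,46682945,2975,NA,0
age-based,NA,644047,94831,153351,46699360,3549,34952,100
precision 2.0%,2.0,622733,84681,156089,46702653,3572,30297,75.4
precision 2.5%,2.5,614230,79620,157723,46703346,3537,27542,66.7
precision 3.0%,3.0,606014,74419,159482,46703788,3503,25290,58.9
precision 3.5%,3.5,598318,69298,161275,46704012,3469,23446,51.9
precision 4.0%,4.0,591244,64384,163045,46704054,3438,21924,45.8
precision 4.5%,4.5,584818,59743,164759,46703950,3409,20659,40.5
precision 5.0%,5.0,579026,55406,166397,46703733,3383,19598,35.9
precision 5.5%,5.5,573830,51379,167947,46703427,3358,18704,31.9
precision 6.0%,6.0,569186,47656,169407,46703054,3336,17947,28.4
precision 6.5%,6.5,565045,44224,170775,46702631,3316,17303,25.4
precision 7.0%,7.0,561358,41065,172055,46702172,3298,16755,22.7
precision 7.5%,7.5,558079,38160,173250,46701687,3281,16289,20.4
precision 8.0%,8.0,555165,35490,174364,46701187,3265,15894,18.4
precision 8.5%,8.5,552577,33036,175403,46700677,3251,15560,16.6
precision 9.0%,9.0,550279,30779,176371,46700163,3238,15281,15.0
precision 9.5%,9.5,548241,28703,177274,46699649,3227,15050,13.6
precision 10.0%,10.0,546432,26791,178116,46699140,3216,14862,12.3
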