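strategy,class,population,harvest,population_verified
1,FC,206,69,TRUE
1,FY,134,25,TRUE
1,FA,532,100,TRUE
1,MC,206,69,TRUE
1,MY,134,45,TRUE
1,YS,172,70,TRUE
1,NS,25,12,TRUE
1,MS,4,2,TRUE
2,FC,116,39,TRUE
2,FY,75,14,TRUE
2,FA,299,55,TRUE
2,MC,116,39,TRUE
2,MY,75,0,TRUE
2,YS,217,1,TRUE
2,NS,204,1,TRUE
2,MS,130,63,TRUE
3,FC,295,208,FALSE
3,FY,83,7,FALSE
3,FA,677,66,FALSE
3,MC,295,208,FALSE
3,MY,83,63,FALSE
3,YS,56,0,FALSE
3,NS,53,0,FALSE
3,MS,50,16,FALSE
4A,FC,202,93,TRUE
4A,FY,101,16,TRUE
4A,FA,510,82,TRUE
4A,MC,202,93,TRUE
4A,MY,101,26,TRUE
4A,YS,171,44,TRUE
4A,NS,69,18,TRUE
4A,MS,47,12,TRUE
4B,FC,190,87,TRUE
4B,FY,95,15,TRUE
4B,FA,480,77,TRUE
4B,MC,190,87,TRUE
4B,MY,95,19,TRUE
4B,YS,185,36,TRUE
4B,NS,95,19,TRUE
4B,MS,50,20,TRUE
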