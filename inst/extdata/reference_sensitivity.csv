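strategy,group,lower,benchmark,upper
1,meat,-267488,2477,272442
1,recreational,-746745,2477,751699
1,browsing,709104,2477,-704150
1,traffic,313798,2477,-308844
2,meat,-1183000,-1024737,-870094
2,recreational,-1506899,-1024737,-546595
2,browsing,-228352,-1024737,-1825142
2,traffic,-674963,-1024737,-1378531
3,meat,27023,296684,583290
3,recreational,-667007,296684,1277320
3,browsing,1067159,296684,-456846
3,traffic,640872,296684,-30559
4A,meat,-434209,-185927,62356
4A,recreational,-917002,-185927,545148
4A,browsing,558439,-185927,-930292
4A,traffic,142029,-185927,-513882
4B,meat,-539705,-303527,-67349
4B,recreational,-1002252,-303527,395198
4B,browsing,450794,-303527,-1057848
4B,traffic,28818,-303527,-635872
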