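size	young
1.258406512339954	47
-0.37102312894076867	32
1.8387393864556485	46
-1.066801586896295	34
-0.2411636418208916	20
0.7057498822001081	82
-2.5177964906887307	26
-0.6348221576592666	15
-0.2552679387173807	45
-0.34271042726735945	14
0.15620344295113384	46
0.034833830535010525	39
-0.41034903453673993	62
1.4080004412289302	61
-1.2426933322727618	24
-0.23264762459806046	11
1.079392300410713	40
0.20126551488611802	19
0.0950309169932963	11
0.5376531353973426	11
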