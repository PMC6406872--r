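Majority protein IDs	Intensity hepa_r1	Intensity hepa_r2	Intensity hepa_r3	MS/MS count hepa_r1	MS/MS count hepa_r2	MS/MS count hepa_r3	Reverse	Potential contaminant
HP0001	48842750	1807258399	0	2	6	4		
HP0002	233014217	122620598	520168955	5	3	6		
HP0003	311545893	24605150	93203892	7	4	6		
HP0004	48289651	4430479	15916247	3	2	6		
HP0005	801778	0	1544171810	6	9	10		
HP0006	371363	27420280	3089109280	2	4	8		
HP0007	9790346	1234064694	317376868	9	11	5		
HP0008	0	664563	127894850	7	9	6		
HP0009	2728012253	685841	172437896	7	4	5		
HP0010	1547998	770460844	121515243	0	4	9		
HP0011;HP0012	41622613	4468596	182925943	7	7	7		
REV_X	12345	23456	34567	4	7	1	+	
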