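125
127
135
137
185
187
190
190
195
200
212
242
245
255
283
316
327
355
373
386
456
482
552
580
700
736
745
750
804
852
884
977
1040
1066
1093
1114
1125
1300
1536
1583
2208
2266
2834
3280
4707
5046
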