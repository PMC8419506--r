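time
49.0370519252767
60.4008256908919
63.0500129238778
74.9371616746907
104.714359799439
114.295060743971
116.732105766926
118.491221165065
121.347284726971
128.083799624098
141.00680975654
146.365427238099
149.564545793581
159.547466104255
164.028930702204
168.506455597465
169.885704637546
172.99170750411
181.579670680566
200.921646951856
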