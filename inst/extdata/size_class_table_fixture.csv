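size_class,stratum,pct,count
Large,active,20.44,28
Medium,active,6.57,9
Small,active,2.92,4
Not Alligator,active,53.28,73
Not Eaten,active,16.79,23
Large,inactive,8.70,2
Medium,inactive,0.00,0
Small,inactive,4.35,1
Not Alligator,inactive,82.61,19
Not Eaten,inactive,4.35,1
Large,Ardea,12.23,17
Medium,Ardea,4.32,6
Small,Ardea,3.60,5
Not Alligator,Ardea,64.03,89
Not Eaten,Ardea,15.83,22
Large,Egretta,61.90,13
Medium,Egretta,14.29,3
Small,Egretta,0.00,0
Not Alligator,Egretta,14.29,3
Not Eaten,Egretta,9.52,2
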