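animal_id,group,sex,trial,age_weeks,weight_g
19061,VPA,M,1,15,167.6
19061,VPA,M,2,16,171.3
19061,VPA,M,3,17,185.2
19061,VPA,M,4,18,190.3
19061,VPA,M,5,19,193.6
19062,VPA,F,1,15,184.2
19062,VPA,F,2,16,187.8
19062,VPA,F,3,17,200.8
19062,VPA,F,4,18,211.2
19062,VPA,F,5,19,217.3
19072,VPA,M,1,15,163.2
19072,VPA,M,2,16,170.0
19072,VPA,M,3,17,186.7
19072,VPA,M,4,18,197.7
19072,VPA,M,5,19,208.5
19143,VPA,F,1,15,187.5
19143,VPA,F,2,16,196.0
19143,VPA,F,3,17,199.0
19143,VPA,F,4,18,211.0
19143,VPA,F,5,19,209.7
19145,VPA,F,1,15,152.3
19145,VPA,F,2,16,157.6
19145,VPA,F,3,17,160.5
19145,VPA,F,4,18,168.8
19145,VPA,F,5,19,173.5
19091,UE,F,1,15,172.2
19091,UE,F,2,16,184.2
19091,UE,F,3,17,199.8
19091,UE,F,4,18,198.6
19091,UE,F,5,19,205.0
19092,UE,M,1,15,170.9
19092,UE,M,2,16,191.0
19092,UE,M,3,17,202.4
19092,UE,M,4,18,207.1
19092,UE,M,5,19,208.3
19093,UE,M,1,15,177.7
19093,UE,M,2,16,195.6
19093,UE,M,3,17,210.9
19093,UE,M,4,18,214.8
19093,UE,M,5,19,209.8
19099,UE,F,1,15,202.7
19099,UE,F,2,16,207.9
19099,UE,F,3,17,215.1
19099,UE,F,4,18,222.3
19099,UE,F,5,19,228.1
19100,UE,F,1,15,187.8
19100,UE,F,2,16,200.8
19100,UE,F,3,17,201.6
19100,UE,F,4,18,206.9
19100,UE,F,5,19,222.1
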