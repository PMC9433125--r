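patient_id,age_years,sex,n_seizures,induction,origin_text
1,11.42,male,1,spontaneous,Right frontal region
2,6.42,female,4,hyperventilation,Frontal lobes
3,11.67,male,1,hyperventilation,Prefrontal lobe
4,5.92,female,5,spontaneous,Frontal lobe
5,6.25,female,2,hyperventilation,Prefrontal lobe
6,5.92,female,2,spontaneous,Frontal lobe
7,6.67,male,1,hyperventilation,"Whole brain (mainly the left central, occipital, and middle temporal regions)"
8,6.42,female,6,hyperventilation,Occipital region
9,9,male,3,hyperventilation,Frontal lobe
10,8.08,female,1,hyperventilation,Prefrontal region
11,8.92,male,1,hyperventilation,Left prefrontal lobe
12,9.33,female,1,hyperventilation,Right mid-posterior temporal region
13,11.33,male,1,spontaneous,Not found
14,8.92,female,3,hyperventilation,Prefrontal lobe
15,8.5,female,1,hyperventilation,Frontal lobe
16,6.17,female,3,spontaneous,Frontal and temporal lobes
17,5.25,female,1,hyperventilation,Not found
18,6,female,3,hyperventilation,Right middle temporal region
19,9,female,1,spontaneous,Frontal lobe
20,7.58,male,1,hyperventilation,"Prefrontal, frontal, and lateral frontal regions"
21,8.75,female,1,hyperventilation,Not found
22,10.75,male,2,spontaneous,Frontal and temporal lobes
23,12.75,female,5,hyperventilation,Frontal lobe
24,6,female,3,spontaneous,Frontal lobe
25,10,female,2,hyperventilation,Prefrontal region
26,10.25,female,2,spontaneous,Frontal and temporal lobes
27,9.42,male,1,hyperventilation,"Prefrontal, frontal, and parafrontal regions"
28,10,female,1,hyperventilation,Not found
29,6.33,female,1,hyperventilation,Left parietal region
30,6.83,male,1,spontaneous,Left occipital and posterior temporal regions
31,12.5,female,1,hyperventilation,Not found
32,6.58,female,4,hyperventilation,Frontal lobe
33,6.42,female,1,hyperventilation,"Prefrontal and parafrontal regions"
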