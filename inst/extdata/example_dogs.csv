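dog_id,breed,cm_grade,sm_grade,f_diameter,ae,angle2,angle3,angle5
A,Griffon Bruxellois,0,0,38,29.9,81.8,77.3,51
B,Griffon Bruxellois,1,0,42.6,31.7,76.9,81.2,46.8
C,Griffon Bruxellois,2,1,37.8,29.4,73.8,83.3,41.5
D,Griffon Bruxellois,2,2,45.6,33.1,63,83.7,44.7
E,Griffon Bruxellois,0,1,41.9,31.9,66,91.5,44.3
F,Griffon Bruxellois,0,2,42.8,34,66,76.6,41.7
G,Griffon Bruxellois,1,2,43.6,33.2,74,86.2,41.3
H,Griffon Bruxellois,2,2,46.8,34.7,62,103.9,42.2
I,Beagle,0,0,42.72,30.66,80.68,61.37,74.95
J,Australian Terrier,0,0,42.26,30.01,80.23,61.67,61.8
K,Australian Terrier,1,0,39.54,29.31,72.4,63.78,62.5
L,Affenpinscher,0,0,40.85,30.95,69.63,88.04,45.75
M,Affenpinscher,0,0,41.08,31.11,69.42,69.02,45.17
N,Affenpinscher,1,0,41.32,30.96,60.29,89.08,46.5
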