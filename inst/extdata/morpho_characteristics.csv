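no,characteristic,type,states,H_reference
1,Tiller,QL,absent:1;present:9,0.04
2,Leaf hairiness,QL,absent:1,0
3,Leaf vein clarity,QL,weak:1;strong:2,0.22
4,Inflorescence stem wax powders,QL,absent:1;present:9,0.43
5,Seed coat color,PQ,yellow:1;brown:2;dark brown:3,0.63
6,Cotyledon color,PQ,light green:2;medium green:3;dark green:4;purple:5,0.85
7,Leaf type,PQ,platy:1;divided leaf:2,0.06
8,Leaf shape,PQ,lanceolate:1;oval:2;elliptic:4;round oval:5;near round:6,1.51
9,Leaf apex,PQ,blunt tip:1;circle:3;broad circle:4,0.73
10,Leaf color,PQ,yellow green:1;light green:2;medium green:3;dark green:4;deep green:5;purple-red:6;purple:7,1.34
11,Leaf margin features,PQ,inward:1;flat:2;outward:3,0.42
12,Petiole shape in horizontal section,PQ,subcircular:1;crescent:2;flat:3,0.11
13,Petiole color,PQ,white:1;green white:2;light green:3;medium green:4;dark green:5;purple:6,1.28
14,Inflorescence stem color,PQ,green:2;light green:3,0.13
15,Flower color,PQ,white:1;light yellow:2;yellow:3;orange red:4,0.38
16,Plant habit,QN,erect:1;erect to semi-erect:2;semi-erect:3;semi-erect to collapse:4;collapse:5,0.98
17,Girdling,QN,absent:1;weak:2;medium:3;strong:4,1.20
18,Plant height,QN,very low:1;very low to low:2;low:3;low to medium:4;medium:5;medium to high:6;high:7;high to very high:8;very high:9,1.90
19,Plumpness of cabbage,QN,loose:1;medium:2;hard:3,0.94
20,Leaf length,QN,very short:1;very short to short:2;short:3;short to medium:4;medium:5;medium to long:6;long:7;long to very long:8;very long:9,1.90
21,Leaf width,QN,very narrow:1;very narrow to narrow:2;narrow:3;narrow to medium:4;medium:5;medium to broad:6;broad:7;broad to very broad:8;very broad:9,1.98
22,Leaf undulation of margin,QN,absent:1;very weak:2,1.39
23,Leaf degree of blistering,QN,absent:1;very weak:2;weak:3;weak to medium:4;medium:5;medium to strong:6;strong:7;strong to very strong:8;very strong:9,1.37
24,Leaf glossiness,QN,absent:1;weak:2;strong:3,0.68
25,Leaf number,QN,very less to less:2;less:3;less to medium:4;medium:5;medium to more:6;more:7;more to very more:8;very more:9,1.77
26,Petiole thickness,QN,very thin:1;very thin to thin:2;thin:3;thin to medium:4;medium:5;medium to thick:6;thick:7;thick to very thick:8;very thick:9,1.97
27,Petiole length,QN,very short to short:2;short:3;short to medium:4;medium:5;medium to long:6;long:7;long to very long:8;very long:9,1.55
28,Petiole width,QN,very narrow:1;very narrow to narrow:2;narrow:3;narrow to medium:4;medium:5;medium to broad:6;broad:7;broad to very broad:8;very broad:9,1.79
29,Bolting period,QN,very early to early:2;early:3;early to medium:4;medium:5;medium to late:6;late:7;late to very late:8;very late:9,1.40
30,Axillary bud generation ability,QN,absent or very weak:1;very weak to weak:2;weak:3;weak to medium:4;medium:5;medium to strong:6;strong:7;strong to very strong:8;very strong:9,2.01
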