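group,dye,marker,size_min,size_max
1,6-FAM,SSR125,110,139
1,6-FAM,SSR283,163,182
1,6-FAM,SSR228,233,274
1,ROX,SSR66,123,148
1,ROX,SSR266,188,305
1,HEX,SSR207,144,214
2,6-FAM,SSR138,150,174
2,6-FAM,SSR45,206,228
2,6-FAM,SSR227,271,355
2,ROX,SSR101,197,225
2,ROX,SSR238,278,325
2,TAMRA,SSR229,114,148
3,6-FAM,SSR256,164,206
3,6-FAM,SSR56,241,270
3,ROX,SSR247,128,149
3,TAMRA,SSR22,155,194
4,6-FAM,SSR221,99,178
4,ROX,SSR90,174,211
4,TAMRA,SSR206,124,207
5,6-FAM,SSR136,153,203
5,6-FAM,SSR198,278,314
5,ROX,SSR192,116,158
5,ROX,SSR222,175,227
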