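mosaic,altitude_m,class,source,raw_count,tp,fp,fn
1,120,species,expert,95,,,
2,120,species,expert,109,,,
3,75,species,expert,63,,,
4,75,species,expert,136,,,
1,120,adult,expert,62,,,
1,120,calf,expert,29,,,
1,120,ghost,expert,4,,,
2,120,adult,expert,59,,,
2,120,calf,expert,25,,,
2,120,ghost,expert,25,,,
3,75,adult,expert,44,,,
3,75,calf,expert,9,,,
3,75,ghost,expert,10,,,
4,75,adult,expert,77,,,
4,75,calf,expert,25,,,
4,75,ghost,expert,34,,,
1,120,species,model,114,91,16,3
2,120,species,model,118,101,24,20
3,75,species,model,103,56,22,1
4,75,species,model,168,129,24,28
1,120,adult,model,77,65,10,0
1,120,calf,model,27,24,1,2
1,120,ghost,model,10,6,5,1
2,120,adult,model,70,51,13,5
2,120,calf,model,26,19,5,3
2,120,ghost,model,22,16,6,12
3,75,adult,model,69,48,12,1
3,75,calf,model,19,11,6,0
3,75,ghost,model,15,12,4,0
4,75,adult,model,102,78,17,0
4,75,calf,model,29,22,2,2
4,75,ghost,model,37,31,5,26
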