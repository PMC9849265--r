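mosaic,altitude_m,reference_class,predicted_class,source,n
1,120,adult,calf,model,1
1,120,adult,ghost,model,3
1,120,calf,adult,model,2
1,120,calf,ghost,model,1
1,120,ghost,adult,model,0
1,120,ghost,calf,model,0
2,120,adult,calf,model,3
2,120,adult,ghost,model,2
2,120,calf,adult,model,3
2,120,calf,ghost,model,1
2,120,ghost,adult,model,9
2,120,ghost,calf,model,1
3,75,adult,calf,model,0
3,75,adult,ghost,model,1
3,75,calf,adult,model,2
3,75,calf,ghost,model,0
3,75,ghost,adult,model,0
3,75,ghost,calf,model,1
4,75,adult,calf,model,1
4,75,adult,ghost,model,3
4,75,calf,adult,model,2
4,75,calf,ghost,model,1
4,75,ghost,adult,model,4
4,75,ghost,calf,model,1
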