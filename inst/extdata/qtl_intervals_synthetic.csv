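chrom,start,end,category
1,5000000,6200000,Milk
1,41000000,42500000,Production
1,78000000,80000000,Reproduction
2,3000000,4100000,Meat and Carcass
2,55000000,57000000,Production
3,12000000,12900000,Health
3,64000000,66000000,Milk
4,8000000,9500000,Exterior
4,70000000,71800000,Reproduction
5,22000000,23500000,Production
5,90000000,91200000,Meat and Carcass
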