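chrom	length
1	274330532
2	151935994
3	132848913
4	130910915
5	104526007
6	170843587
7	121844099
8	138966237
9	139512083
10	69359453
11	79169978
12	61602749
13	208334590
14	141755446
15	140412725
16	79944280
17	63494081
18	55982971
X	125939595
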