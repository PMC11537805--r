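"setup","replicate","generation","males_total","males_white","females_total","females_white","females_het","females_hom2"
"I",1,1,356,0,369,0,,
"I",1,2,379,203,294,0,162,132
"I",1,3,290,89,370,74,,
"I",1,8,306,228,313,197,,
"I",1,12,326,287,359,299,,
"I",1,20,299,296,265,263,,
"I",2,1,346,0,287,0,,
"I",2,2,259,128,339,0,173,166
"I",2,3,314,93,335,58,,
"I",2,8,280,220,392,214,,
"I",2,12,282,254,296,250,,
"I",2,20,364,358,267,261,,
"II",1,1,257,257,341,0,,
"II",1,2,345,183,368,215,153,0
"II",1,3,373,296,362,170,,
"II",1,8,252,234,384,323,,
"II",1,12,307,302,324,307,,
"II",1,20,252,250,252,251,,
"II",2,1,286,286,314,0,,
"II",2,2,255,132,361,207,154,0
"II",2,3,398,321,302,157,,
"II",2,8,271,253,317,281,,
"II",2,12,268,260,275,259,,
"II",2,20,289,289,348,346,,
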