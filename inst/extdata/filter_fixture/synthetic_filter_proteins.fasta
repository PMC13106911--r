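>sp|HUMA1|GA1_HUMAN Synthetic protein OS=Homo sapiens OX=9606 GN=GA1 PE=1 SV=1
MAAAAAKGGGGGGRTTTTTTK
>sp|HUMA2|GA2_HUMAN Synthetic protein OS=Homo sapiens OX=9606 GN=GA2 PE=1 SV=1
MAAAAAKGGGGGGRTTTTTTK
>sp|HUMA3|GA3_HUMAN Synthetic protein OS=Homo sapiens OX=9606 GN=GA3 PE=1 SV=1
MAAAAAKGGGGGGRTTTTTTK
>sp|HUMA4|GA4_HUMAN Synthetic protein OS=Homo sapiens OX=9606 GN=GA4 PE=1 SV=1
MAAAAAKGGGGGGRTTTTTTK
>sp|HUMA5|GA5_HUMAN Synthetic protein OS=Homo sapiens OX=9606 GN=GA5 PE=1 SV=1
MAAAAAKGGGGGGRTTTTTTK
>sp|HUMA6|GA6_HUMAN Synthetic protein OS=Homo sapiens OX=9606 GN=GA6 PE=1 SV=1
MAAAAAKGGGGGGRTTTTTTK
>tr|BOVA1|BT1_BOVIN Synthetic protein OS=Bos taurus OX=9913 GN=BT1 PE=1 SV=1
MAAAAAKGGGGGGRTTTTTTK
>sp|KERA1|KRT10_HUMAN Synthetic protein OS=Homo sapiens OX=9606 GN=KRT10 PE=1 SV=1
MAAAAAKGGGGGGRTTTTTTK
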