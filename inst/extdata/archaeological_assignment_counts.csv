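site,tooth,assigned,n
Juikentta,m1,forest,1
Markkina,m1,mountain,19
Markkina,m1,forest,2
Nukkumajoki,m1,mountain,7
Nukkumajoki,m1,forest,3
Pappila,m1,mountain,4
Juikentta,m2,forest,1
Markkina,m2,mountain,21
Markkina,m2,forest,2
Nukkumajoki,m2,mountain,13
Nukkumajoki,m2,forest,5
Pappila,m2,mountain,12
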