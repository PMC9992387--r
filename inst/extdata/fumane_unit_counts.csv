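unit,taxon,nisp,mni,mni_F,mni_J,mni_SAd,mni_Ad,mni_S,habitat,rank
A2-A1,Bos/Bison,3,2,0,1,0,1,0,plain,high
A2-A1,Capra ibex,136,9,1,2,1,4,1,mountain,high
A2-A1,Rupicapra rupicapra,54,4,0,2,0,2,0,mountain,low
A2-A1,Megaloceros giganteus,8,2,0,1,0,1,0,plain,high
A2-A1,Cervus elaphus,44,5,0,2,0,3,0,plain,high
A2-A1,Capreolus capreolus,18,2,0,1,0,1,0,plain,low
D3,Bos/Bison,1,1,0,0,0,1,0,plain,high
D3,Capra ibex,27,4,0,2,0,2,0,mountain,high
D3,Rupicapra rupicapra,30,5,0,2,1,2,0,mountain,low
D3,Megaloceros giganteus,4,1,0,0,0,1,0,plain,high
D3,Cervus elaphus,10,1,0,0,0,1,0,plain,high
D3,Capreolus capreolus,7,3,0,2,0,1,0,plain,low
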