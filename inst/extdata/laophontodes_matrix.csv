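"id","description","sarsi","scottorum","volkerlehmanskii","georgei","gertraudae","spongiosus","mourois","typicus","monsmaris","macclintocki","sabinegeorgeae","whitsoni"
1,"A2 exopod represented by tiny seta [with 1 small, knob-like segment bearing 1 small seta]",1,1,1,1,1,1,1,1,1,1,1,1
2,"A1 male 6-segmented, chirocer [7-segmented, subchirocer]",?,1,1,1,1,1?,1,1,1,0?,0,0
3,"P4 female enp-2 lacking outer seta [seta present]",1,1,1,1,1,1,1,1,1,0,0,0*
4,"P3exp-3 with at most 1 inner seta [with 2 setae]",1,1,1,1,1,1,1,1,0,1,0,0
5,"P4exp-3 with at most 1 inner seta [with 2 setae]",1,1,1,1,1,1,1,1,0,1,0,0
6,"P2exp-2 lacking inner seta [seta present]",1,1,1,1,1,1,1,1,0,0,0,0
7,"P3exp-2 lacking inner seta [seta present]",1,1,1,1,1,1,1,1,0,0,0,0
8,"P2exp-3 lacking inner seta [seta present]",1,1,1,1,1,1,0,0,0,0,0,0
9,"P4exp-3 inner apical seta trimmed down, flexible [seta almost identical with outer apical element]",1,1,1,1,0,0,0,0,0,0,0,0
10,"P2exp-3 inner apical seta trimmed down, flexible [seta almost identical with outer apical element]",1,1,1,0,0,0,0,0,0,0,0,0
11,"P3exp-3 inner apical seta trimmed down, flexible [seta almost identical with outer apical element]",1,1,1,0,0,0,0,0,0,0,0,0
12,"P2exp-3 down-trimmed inner apical seta bare [seta biplumose]",1,1,0,0,0,0,0,0,0,0,0,0
13,"P3exp-3 down-trimmed inner apical seta bare [seta biplumose]",1,1,0,0,0,0,0,0,0,0,0,0
14,"P4exp-3 down-trimmed inner apical seta bare [seta biplumose]",1,1,0,0,0,0,0,0,0,0,0,0
15,"P5 female inner baseoendopodal seta of fish-bone aspect [seta bipinnate]",1,0,0,0,0,0,0,0,0,0,0,0
16,"Body flattened [cylindrical]",0,1,0,0,0,0,0,0,0,0,0,0
17,"Body somites laterally extended [not extended]",0,1,0,0,0,1,0,0,0,0,0,0
18,"Anal operculum: posterior margin strongly serrated [with spinules]",0,0,1,0,0,0,0,0,0,0,0,0
19,"Furcal tube pore long, displaced subapically [tube pore small, near furcal base]",0,0,1,0,0,0,0,0,0,0,0,0
20,"P1 inner basal seta strongly diminished in size [of moderate length]",0,0,1,0,0,0,0,0,0,0,0,0
21,"P1 outer basal seta with STE [lacking STE]",0,0,1,0,0,0,0,0,0,0,0,0
22,"P1exp-1 outer seta with STE [lacking STE]",0,0,1,0,0,0,0,0,0,0,0,0
23,"P5 male exopod: subapical outer seta with STE [lacking STE]",0,0,1,0,0,0,0,0,0,0,0,0
24,"P1enp-2 apical long seta lost geniculation [seta geniculated]",0,0,0,1,0,0,0,0,0,0,0,0
25,"P4 endopod 1-segmented [2-segmented]",0,0,0,1,0,0,0,0,0,0,0,0
26,"P4enp-2 lacking inner seta [seta present]",0,0,0,0,1,0,0,0,0,0,0,0*
27,"Abdominal somites except telson dorsally with H-like cuticular structures [such structures absent]",0,0,0,0,0,1,0,0,0,0,0,0
28,"P2exp-3 inner apical seta bare [seta biplumose]",0,0,0,0,0,0,1,1,0,0,0,0
29,"P3 male enp-3 bulged out on its inner margin [margin straight]",0,0,0,0,0,0,1,0,0,0,0,0
30,"Mxp lacking tiny seta accompanying claw [tiny seta present]",0,0,0,?,0,0,0,1,0,1,0,0
31,"Mxp extremely strengthened [mxp of moderate size]",0,0,0,0,0,0,0,0,1,0,0,0
32,"Telson overlapped by previous somite [not overlapped]",0,0,0,0,0,0,0,0,1,0,0,0
33,"Rostrum frontally with tuft of long setules [no setular tuft]",0,0,0,0,0,0,0,0,0,0,1,0
34,"Abdominal somites except telson dorsally with paired cuticular longitudinal ridges [such ridges absent]",0,0,0,0,0,0,0,0,0,0,1,0
35,"Abdominal somites except telson dorsally with pairs of long tube pores [paired tube pores, if present, small]",0,0,0,0,0,0,0,0,0,0,1,0
36,"FR mid-laterally with accessory long tube pore [lacking accessory tube pore]",0,0,0,0,0,0,0,0,0,0,1,0
37,"FR setae I and II displaced subapically [arising mid-laterally]",0,0,0,0,0,0,0,0,0,0,1,0
38,"P5 male exopod: proximal lateral seta with STE [lacking STE]",0,0,0,0,0,0,0,0,0,0,0,1
39,"P5 male exopod: subapical inner seta with STE [lacking STE]",0,0,0,0,0,0,0,0,0,0,0,1
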