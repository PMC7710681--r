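# Diagnostic key to the 12 analysed species of Laophontodes.
# Transcribed couplet-for-couplet; the first lead of each couplet is the
# un-dashed printed line. cphth = cephalothorax, FR = furcal rami,
# Mxp = maxilliped, STE = seta with tube extension.
start: 1
couplets:
- id: 1
  a:
    text: "Body slender, cylindrical; cphth about 1/4th of total body length (incl. FR)"
    goto: 2
  b:
    text: "Body compact, partially compressed dorsoventrally; cphth about 1/3rd of total body length (incl. FR)"
    taxon: scottorum
- id: 2
  a:
    text: "Second antennular segment with flat posterior surface"
    goto: 3
  b:
    text: "Second antennular segment with posterior surface produced into bump"
    goto: 4
- id: 3
  a:
    text: "Mxp of moderate size; P3 and P4exp-3 with 1 inner seta; telson not overlapped by preceding somite dorsally; male antennule subchirocer"
    taxon: macclintocki
  b:
    text: "Mxp extremely strengthened; P3 and P4exp-3 with 2 inner setae; telson overlapped by preceding somite; male antennule chirocer"
    taxon: monsmaris
- id: 4
  a:
    text: "Apical claw on P1enp-2 narrow and thin; male antennule subchirocer"
    goto: 5
  b:
    text: "Apical claw on P1enp-2 wide and thickened; male antennule chirocer or subchirocer"
    goto: 6
- id: 5
  a:
    text: "Pedigerous and abdominal somites dorsally with fine ripples; P2-P4exp-3 with 1:2:2 inner setae"
    taxon: whitsoni
  b:
    text: "No ripples on body somites, abdominal somites except telson dorsally with H-like cuticular structures; P2-P4 with 0:0:1 inner setae"
    taxon: spongiosus
- id: 6
  a:
    text: "P2 and P3exp-2 with 1 inner seta, P3 and P4exp-3 with 2 inner setae; rostrum with setulose tuft frontally; pedigerous and abdominal somites with fine ripples dorsally; abdominal somites except telson with paired cuticular ridges dorsally"
    taxon: sabinegeorgeae
  b:
    text: "These characters not combined"
    goto: 7
- id: 7
  a:
    text: "P4exp-3 inner apical seta short, flagelliform, bare"
    goto: 8
  b:
    text: "P4exp-3 inner apical seta long, biplumose"
    goto: 10
- id: 8
  a:
    text: "P2 and P3exp-3 inner apical seta short, flagelliform, bare"
    taxon: sarsi
  b:
    text: "P2 and P3exp-3 inner apical seta long, biplumose"
    goto: 9
- id: 9
  a:
    text: "P2-P4exp-3 without inner setae; P4 endopod 1-segmented; inner margin of male P3enp-3 straight"
    taxon: georgei
  b:
    text: "P2-P4exp-3 with 1 inner seta; P4 endopod 2-segmented; inner margin of male P3enp-3 bulged out"
    taxon: mourois
- id: 10
  a:
    text: "P1exp-1 outer spine unipinnate, comb-shaped, with strong outer pinnae; anal operculum with row of fine spinules on apical margin"
    goto: 11
  b:
    text: "P1exp-1 outer spine bipinnate, of normal shape; anal operculum with few strong spinules on apical margin"
    taxon: volkerlehmanskii
- id: 11
  a:
    text: "P2-P4-bearing somites with fine ripples dorsally; maxillipedal claw without accompanying minute seta; female P5 baseoendopodal inner seta fish-bone-like"
    taxon: typicus
  b:
    text: "P2-P4-bearing somites without ripples; maxillipedal claw with accompanying minute seta; female P5 baseoendopodal inner seta bipinnate, of normal shape"
    taxon: gertraudae
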