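laterality,hour,quadrant,icdo3,omop_id
L,12,upper_outer,C50.4,35941054
L,1,upper_outer,C50.4,35941054
L,2,upper_outer,C50.4,35941054
L,3,lower_outer,C50.5,35941055
L,4,lower_outer,C50.5,35941055
L,5,lower_outer,C50.5,35941055
L,6,lower_inner,C50.3,35941053
L,7,lower_inner,C50.3,35941053
L,8,lower_inner,C50.3,35941053
L,9,upper_inner,C50.2,35941052
L,10,upper_inner,C50.2,35941052
L,11,upper_inner,C50.2,35941052
R,12,upper_inner,C50.2,35941052
R,1,upper_inner,C50.2,35941052
R,2,upper_inner,C50.2,35941052
R,3,lower_inner,C50.3,35941053
R,4,lower_inner,C50.3,35941053
R,5,lower_inner,C50.3,35941053
R,6,lower_outer,C50.5,35941055
R,7,lower_outer,C50.5,35941055
R,8,lower_outer,C50.5,35941055
R,9,upper_outer,C50.4,35941054
R,10,upper_outer,C50.4,35941054
R,11,upper_outer,C50.4,35941054
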