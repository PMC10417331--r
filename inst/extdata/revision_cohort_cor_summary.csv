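stage,measure,mean,sd,unit
preop,x,86.3,8.7,mm
preop,y,71.7,9.6,mm
preop,z,52.2,4.8,mm
preop,inclination,55.7,15.4,deg
preop,anteversion,21.1,9.7,deg
planned,x,86.0,7.8,mm
planned,y,71.3,11.8,mm
planned,z,51.8,2.3,mm
planned,inclination,47.7,5.6,deg
planned,anteversion,17.3,4.1,deg
postop,x,87.5,8.6,mm
postop,y,66.6,10.5,mm
postop,z,53.7,4.5,mm
postop,inclination,51.6,5.3,deg
postop,anteversion,15.4,5.2,deg
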