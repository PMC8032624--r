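# Human (70 kg adult) reference physiology for the 14-compartment PBK model.
# Tissue volumes and blood flows transcribed from the standard reference
# compendium lineage (Jones & Rowland-Yeo 2013; Brown et al. 1997).
# Reference-compendium values, user-overridable. Units: L, L/h, kg.
species_name: human
body_weight: 70
cardiac_output: 336
renal_clearance: 6.7
tissue_volumes:
  liver: 1.82
  gut: 1.19
  fat: 14.98
  muscle: 28.0
  skin: 2.59
  bone: 5.95
  brain: 1.40
  heart: 0.35
  kidney: 0.28
  lung: 0.56
  spleen: 0.14
  venous_blood: 3.87
  arterial_blood: 1.66
  rest: 4.76
blood_flows:
  fat: 16.8
  muscle: 57.1
  skin: 19.5
  bone: 16.8
  brain: 40.3
  heart: 13.4
  kidney: 63.8
  spleen: 6.7
  gut: 53.8
  liver: 21.8
  rest: 26.0
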