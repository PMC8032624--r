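# Rat reference physiology for the 14-compartment PBK model.
# Tissue volumes and blood flows transcribed from the standard reference
# compendium lineage (Jones & Rowland-Yeo 2013; Brown et al. 1997).
# These are reference-compendium values, not values printed in any single
# study; all are user-overridable. Units: volumes L, flows L/h, body weight kg.
species_name: rat
body_weight: 0.25
cardiac_output: 4.98
renal_clearance: 0.078
tissue_volumes:
  liver: 0.00915
  gut: 0.00675
  fat: 0.01900
  muscle: 0.10110
  skin: 0.04760
  bone: 0.01825
  brain: 0.001425
  heart: 0.000825
  kidney: 0.001825
  lung: 0.00125
  spleen: 0.0005
  venous_blood: 0.01295
  arterial_blood: 0.00555
  rest: 0.01360
blood_flows:
  # arterial inflows; liver entry is the hepatic artery only (the portal
  # vein adds the gut and spleen outflows inside the model)
  fat: 0.3490
  muscle: 1.3840
  skin: 0.2890
  bone: 0.6080
  brain: 0.0996
  heart: 0.2440
  kidney: 0.7020
  spleen: 0.0498
  gut: 0.7520
  liver: 0.1195
  rest: 0.3831
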