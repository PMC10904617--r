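# Reference adult virtual subject for the whole-body PBPK model.
# Volumes and blood flows are a config artifact assembled from standard
# reference-human compilations (healthy ~70 kg adult, cardiac output
# 6 L/min of blood), not a measured ground truth. rest_of_body closes the
# volume balance against body mass and the flow balance against cardiac
# output.
name: reference_adult
body_weight_kg: 70
cardiac_output_L_h: 360
gut_lumen_radius_cm: 1.25
blood:
  venous_L: 3.69
  arterial_L: 1.84
  plasma_L: 3.00
tissues:
  lung:         {volume_L: 0.53,  flow_L_h: 360.0}
  heart:        {volume_L: 0.33,  flow_L_h: 14.4}
  brain:        {volume_L: 1.40,  flow_L_h: 43.2}
  muscle:       {volume_L: 28.00, flow_L_h: 61.2}
  adipose:      {volume_L: 15.00, flow_L_h: 18.0}
  skin:         {volume_L: 2.60,  flow_L_h: 18.0}
  spleen:       {volume_L: 0.18,  flow_L_h: 10.8}
  pancreas:     {volume_L: 0.10,  flow_L_h: 3.6}
  liver:        {volume_L: 1.80,  flow_L_h: 23.4}
  stomach:      {volume_L: 0.15,  flow_L_h: 3.6}
  gut:          {volume_L: 1.20,  flow_L_h: 50.4}
  bone:         {volume_L: 6.00,  flow_L_h: 18.0}
  kidney:       {volume_L: 0.31,  flow_L_h: 68.4}
  rest_of_body: {volume_L: 6.87,  flow_L_h: 27.0}
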