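{"n_channels":9,"postures":["rest","spread","finger pointing","scissor sign","V sign","O.K. sign","thumb up (hook)","cylindrical grasp","spherical grasp","lateral pinch","palmar pinch","tip pinch"],"amplitude_matrix":[0.08,0.15,0.4,0.35,0.3,0.6,0.25,0.8,0.75,0.5,0.6,0.58,0.08,0.9,0.8,0.7,0.75,0.3,0.35,0.3,0.35,0.25,0.25,0.22,0.08,0.7,0.3,0.55,0.6,0.15,0.2,0.15,0.2,0.12,0.12,0.14,0.08,0.55,0.2,0.25,0.3,0.5,0.8,0.15,0.18,0.6,0.45,0.5,0.08,0.12,0.2,0.18,0.15,0.4,0.2,0.5,0.55,0.4,0.35,0.33,0.08,0.12,0.15,0.15,0.12,0.25,0.2,0.5,0.45,0.3,0.28,0.3,0.08,0.5,0.3,0.25,0.35,0.3,0.4,0.25,0.28,0.35,0.3,0.28,0.08,0.5,0.25,0.3,0.3,0.2,0.3,0.3,0.32,0.22,0.2,0.22,0.08,0.2,0.15,0.15,0.15,0.25,0.3,0.4,0.45,0.3,0.28,0.26],"spectral_centroid_matrix":[100,140,125,150,115,135,105,110,135,120,110,140,102.5,142.5,127.5,152.5,117.5,137.5,107.5,112.5,137.5,122.5,112.5,142.5,105,145,130,155,120,140,110,115,140,125,115,145,107.5,147.5,132.5,157.5,122.5,142.5,112.5,117.5,142.5,127.5,117.5,147.5,110,150,135,160,125,145,115,120,145,130,120,150,112.5,152.5,137.5,162.5,127.5,147.5,117.5,122.5,147.5,132.5,122.5,152.5,115,155,140,165,130,150,120,125,150,135,125,155,117.5,157.5,142.5,167.5,132.5,152.5,122.5,127.5,152.5,137.5,127.5,157.5,120,160,145,170,135,155,125,130,155,140,130,160],"sigma_trial":[0.5,0.25,0.1],"crosstalk_lambda":0.05,"rest_amplitude":0.05,"fs":1926,"trial_s":5,"sessions_per_day":10,"seed":1,"channel_names":["FDS","ED","EDM","EP","FCR","FCU","ECR","ECU","BR"]}
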