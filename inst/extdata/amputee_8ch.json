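{"n_channels":8,"postures":["rest","spread","finger pointing","scissor sign","V sign","O.K. sign","thumb up (hook)","cylindrical grasp","spherical grasp","lateral pinch","palmar pinch","tip pinch"],"amplitude_matrix":[0.08,0.2,0.15,0.19125,0.15,0.25,0.3,0.3625,0.45,0.3375,0.28,0.21875,0.08,0.12,0.2,0.23625,0.15,0.4,0.2,0.4625,0.55,0.4375,0.35,0.27375,0.08,0.5,0.3,0.26125,0.35,0.3,0.4,0.2875,0.28,0.3125,0.3,0.26875,0.08,0.9,0.8,0.52,0.75,0.3,0.35,0.28125,0.35,0.26875,0.25,0.4,0.08,0.5,0.25,0.27,0.3,0.2,0.3,0.27,0.32,0.25,0.2,0.25,0.144,0.2,0.4,0.429,0.32,0.56,0.28,0.63,0.68,0.57,0.56,0.475,0.08,0.15,0.4,0.43625,0.3,0.6,0.25,0.6875,0.75,0.6125,0.6,0.49375,0.08,0.12,0.15,0.20625,0.12,0.25,0.2,0.425,0.45,0.375,0.28,0.24375],"spectral_centroid_matrix":[120,160,145,166.25,135,155,125,133.75,155,136.25,130,163.75,110,150,135,156.25,125,145,115,123.75,145,126.25,120,153.75,115,155,140,161.25,130,150,120,128.75,150,131.25,125,158.75,102.5,142.5,127.5,148.75,117.5,137.5,107.5,116.25,137.5,118.75,112.5,146.25,117.5,157.5,142.5,163.75,132.5,152.5,122.5,131.25,152.5,133.75,127.5,161.25,95,135,120,141.25,110,130,100,108.75,130,111.25,105,138.75,100,140,125,146.25,115,135,105,113.75,135,116.25,110,143.75,112.5,152.5,137.5,158.75,127.5,147.5,117.5,126.25,147.5,128.75,122.5,156.25],"sigma_trial":[0.6,0.45,0.3,0.2,0.12],"crosstalk_lambda":0.05,"rest_amplitude":0.05,"fs":1926,"trial_s":5,"sessions_per_day":10,"seed":1,"channel_names":["BR","FCR","ECR","ED","ECU","FDP","FDS","FCU"]}
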