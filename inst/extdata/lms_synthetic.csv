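"measure","sex","age_years","L","M","S"
"bmi","female",10,-1.72,20.1,0.115
"bmi","female",10.5,-1.71,20.325,0.115
"bmi","female",11,-1.7,20.55,0.115
"bmi","female",11.5,-1.69,20.775,0.115
"bmi","female",12,-1.68,21,0.115
"bmi","female",12.5,-1.67,21.225,0.115
"bmi","female",13,-1.66,21.45,0.115
"bmi","female",13.5,-1.65,21.675,0.115
"bmi","female",14,-1.64,21.9,0.115
"bmi","female",14.5,-1.63,22.125,0.115
"bmi","female",15,-1.62,22.35,0.115
"bmi","female",15.5,-1.61,22.575,0.115
"bmi","female",16,-1.6,22.8,0.115
"bmi","female",16.5,-1.59,23.025,0.115
"bmi","female",17,-1.58,23.25,0.115
"bmi","female",17.5,-1.57,23.475,0.115
"bmi","female",18,-1.56,23.7,0.115
"bmi","female",18.5,-1.55,23.925,0.115
"bmi","female",19,-1.54,24.15,0.115
"bmi","female",19.5,-1.53,24.375,0.115
"bmi","female",20,-1.52,24.6,0.115
"bmi","female",20.5,-1.51,24.825,0.115
"bmi","female",21,-1.5,25.05,0.115
"bmi","female",21.5,-1.49,25.275,0.115
"bmi","female",22,-1.48,25.5,0.115
"bmi","male",10,-1.72,19.75,0.125
"bmi","male",10.5,-1.71,19.975,0.125
"bmi","male",11,-1.7,20.2,0.125
"bmi","male",11.5,-1.69,20.425,0.125
"bmi","male",12,-1.68,20.65,0.125
"bmi","male",12.5,-1.67,20.875,0.125
"bmi","male",13,-1.66,21.1,0.125
"bmi","male",13.5,-1.65,21.325,0.125
"bmi","male",14,-1.64,21.55,0.125
"bmi","male",14.5,-1.63,21.775,0.125
"bmi","male",15,-1.62,22,0.125
"bmi","male",15.5,-1.61,22.225,0.125
"bmi","male",16,-1.6,22.45,0.125
"bmi","male",16.5,-1.59,22.675,0.125
"bmi","male",17,-1.58,22.9,0.125
"bmi","male",17.5,-1.57,23.125,0.125
"bmi","male",18,-1.56,23.35,0.125
"bmi","male",18.5,-1.55,23.575,0.125
"bmi","male",19,-1.54,23.8,0.125
"bmi","male",19.5,-1.53,24.025,0.125
"bmi","male",20,-1.52,24.25,0.125
"bmi","male",20.5,-1.51,24.475,0.125
"bmi","male",21,-1.5,24.7,0.125
"bmi","male",21.5,-1.49,24.925,0.125
"bmi","male",22,-1.48,25.15,0.125
"waist","female",10,-0.8,62.5,0.095
"waist","female",10.5,-0.8,63.275,0.095
"waist","female",11,-0.8,64.05,0.095
"waist","female",11.5,-0.8,64.825,0.095
"waist","female",12,-0.8,65.6,0.095
"waist","female",12.5,-0.8,66.375,0.095
"waist","female",13,-0.8,67.15,0.095
"waist","female",13.5,-0.8,67.925,0.095
"waist","female",14,-0.8,68.7,0.095
"waist","female",14.5,-0.8,69.475,0.095
"waist","female",15,-0.8,70.25,0.095
"waist","female",15.5,-0.8,71.025,0.095
"waist","female",16,-0.8,71.8,0.095
"waist","female",16.5,-0.8,72.575,0.095
"waist","female",17,-0.8,73.35,0.095
"waist","female",17.5,-0.8,74.125,0.095
"waist","female",18,-0.8,74.9,0.095
"waist","female",18.5,-0.8,75.675,0.095
"waist","female",19,-0.8,76.45,0.095
"waist","female",19.5,-0.8,77.225,0.095
"waist","female",20,-0.8,78,0.095
"waist","female",20.5,-0.8,78.775,0.095
"waist","female",21,-0.8,79.55,0.095
"waist","female",21.5,-0.8,80.325,0.095
"waist","female",22,-0.8,81.1,0.095
"waist","male",10,-0.9,64.7,0.105
"waist","male",10.5,-0.9,65.475,0.105
"waist","male",11,-0.9,66.25,0.105
"waist","male",11.5,-0.9,67.025,0.105
"waist","male",12,-0.9,67.8,0.105
"waist","male",12.5,-0.9,68.575,0.105
"waist","male",13,-0.9,69.35,0.105
"waist","male",13.5,-0.9,70.125,0.105
"waist","male",14,-0.9,70.9,0.105
"waist","male",14.5,-0.9,71.675,0.105
"waist","male",15,-0.9,72.45,0.105
"waist","male",15.5,-0.9,73.225,0.105
"waist","male",16,-0.9,74,0.105
"waist","male",16.5,-0.9,74.775,0.105
"waist","male",17,-0.9,75.55,0.105
"waist","male",17.5,-0.9,76.325,0.105
"waist","male",18,-0.9,77.1,0.105
"waist","male",18.5,-0.9,77.875,0.105
"waist","male",19,-0.9,78.65,0.105
"waist","male",19.5,-0.9,79.425,0.105
"waist","male",20,-0.9,80.2,0.105
"waist","male",20.5,-0.9,80.975,0.105
"waist","male",21,-0.9,81.75,0.105
"waist","male",21.5,-0.9,82.525,0.105
"waist","male",22,-0.9,83.3,0.105
"waist_height","female",10,-1.1,0.464,0.075
"waist_height","female",10.5,-1.1,0.463,0.075
"waist_height","female",11,-1.1,0.462,0.075
"waist_height","female",11.5,-1.1,0.461,0.075
"waist_height","female",12,-1.1,0.46,0.075
"waist_height","female",12.5,-1.1,0.459,0.075
"waist_height","female",13,-1.1,0.458,0.075
"waist_height","female",13.5,-1.1,0.457,0.075
"waist_height","female",14,-1.1,0.456,0.075
"waist_height","female",14.5,-1.1,0.455,0.075
"waist_height","female",15,-1.1,0.454,0.075
"waist_height","female",15.5,-1.1,0.453,0.075
"waist_height","female",16,-1.1,0.452,0.075
"waist_height","female",16.5,-1.1,0.451,0.075
"waist_height","female",17,-1.1,0.45,0.075
"waist_height","female",17.5,-1.1,0.449,0.075
"waist_height","female",18,-1.1,0.448,0.075
"waist_height","female",18.5,-1.1,0.447,0.075
"waist_height","female",19,-1.1,0.446,0.075
"waist_height","female",19.5,-1.1,0.445,0.075
"waist_height","female",20,-1.1,0.444,0.075
"waist_height","female",20.5,-1.1,0.443,0.075
"waist_height","female",21,-1.1,0.442,0.075
"waist_height","female",21.5,-1.1,0.441,0.075
"waist_height","female",22,-1.1,0.44,0.075
"waist_height","male",10,-1.1,0.472,0.075
"waist_height","male",10.5,-1.1,0.471,0.075
"waist_height","male",11,-1.1,0.47,0.075
"waist_height","male",11.5,-1.1,0.469,0.075
"waist_height","male",12,-1.1,0.468,0.075
"waist_height","male",12.5,-1.1,0.467,0.075
"waist_height","male",13,-1.1,0.466,0.075
"waist_height","male",13.5,-1.1,0.465,0.075
"waist_height","male",14,-1.1,0.464,0.075
"waist_height","male",14.5,-1.1,0.463,0.075
"waist_height","male",15,-1.1,0.462,0.075
"waist_height","male",15.5,-1.1,0.461,0.075
"waist_height","male",16,-1.1,0.46,0.075
"waist_height","male",16.5,-1.1,0.459,0.075
"waist_height","male",17,-1.1,0.458,0.075
"waist_height","male",17.5,-1.1,0.457,0.075
"waist_height","male",18,-1.1,0.456,0.075
"waist_height","male",18.5,-1.1,0.455,0.075
"waist_height","male",19,-1.1,0.454,0.075
"waist_height","male",19.5,-1.1,0.453,0.075
"waist_height","male",20,-1.1,0.452,0.075
"waist_height","male",20.5,-1.1,0.451,0.075
"waist_height","male",21,-1.1,0.45,0.075
"waist_height","male",21.5,-1.1,0.449,0.075
"waist_height","male",22,-1.1,0.448,0.075
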