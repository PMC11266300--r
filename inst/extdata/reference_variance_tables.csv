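table,group,side,mode,A,B
complete_femur,group_1,left,1,93.5,93.5
complete_femur,group_1,left,2,5.62,99.1
complete_femur,group_1,left,3,0.34,99.5
complete_femur,group_1,left,4,0.17,99.6
complete_femur,group_1,left,5,0.11,99.7
complete_femur,group_2,left,1,91.3,91.3
complete_femur,group_2,left,2,6.06,97.3
complete_femur,group_2,left,3,1.49,98.8
complete_femur,group_2,left,4,0.39,99.2
complete_femur,group_2,left,5,0.25,99.5
complete_femur,group_3,left,1,91.7,91.7
complete_femur,group_3,left,2,7.6,99.3
complete_femur,group_3,left,3,0.22,99.5
complete_femur,group_3,left,4,0.15,99.6
complete_femur,group_3,left,5,0.12,99.8
complete_femur,group_4,left,1,73.5,73.5
complete_femur,group_4,left,2,23.6,97.1
complete_femur,group_4,left,3,1.08,98.2
complete_femur,group_4,left,4,0.82,99
complete_femur,group_4,left,5,0.4,99.4
complete_femur,group_5,left,1,93.8,93.8
complete_femur,group_5,left,2,5.04,98.9
complete_femur,group_5,left,3,0.35,99.2
complete_femur,group_5,left,4,0.28,99.5
complete_femur,group_5,left,5,0.13,99.6
complete_femur,group_6,left,1,90.1,90.1
complete_femur,group_6,left,2,8.54,98.6
complete_femur,group_6,left,3,0.67,99.3
complete_femur,group_6,left,4,0.36,99.6
complete_femur,group_6,left,5,0.11,99.7
complete_femur,group_1,right,1,96.4,96.4
complete_femur,group_1,right,2,3.01,99.4
complete_femur,group_1,right,3,0.2,99.6
complete_femur,group_1,right,4,0.14,99.7
complete_femur,group_1,right,5,0.07,99.8
complete_femur,group_2,right,1,74.2,74.2
complete_femur,group_2,right,2,19.6,93.8
complete_femur,group_2,right,3,3.53,97.3
complete_femur,group_2,right,4,1.57,98.9
complete_femur,group_2,right,5,0.5,99.4
complete_femur,group_3,right,1,92.9,92.9
complete_femur,group_3,right,2,6.22,99.2
complete_femur,group_3,right,3,0.29,99.5
complete_femur,group_3,right,4,0.24,99.7
complete_femur,group_3,right,5,0.09,99.8
complete_femur,group_4,right,1,77.1,77.1
complete_femur,group_4,right,2,19.6,96.8
complete_femur,group_4,right,3,1.53,98.3
complete_femur,group_4,right,4,0.65,98.9
complete_femur,group_4,right,5,0.35,99.3
complete_femur,group_5,right,1,89.5,89.5
complete_femur,group_5,right,2,6.72,96.2
complete_femur,group_5,right,3,2.95,99.2
complete_femur,group_5,right,4,0.28,99.5
complete_femur,group_5,right,5,0.2,99.7
complete_femur,group_6,right,1,87.3,87.3
complete_femur,group_6,right,2,11.2,98.5
complete_femur,group_6,right,3,0.8,99.3
complete_femur,group_6,right,4,0.33,99.6
complete_femur,group_6,right,5,0.14,99.7
regions,femur_condyles,left,1,80.4,80.4
regions,femur_condyles,left,2,7.46,87.9
regions,femur_condyles,left,3,3.55,91.5
regions,femur_condyles,left,4,3.05,94.5
regions,femur_condyles,left,5,0.92,95.4
regions,femoral_head,left,1,85.2,85.2
regions,femoral_head,left,2,3.21,88.4
regions,femoral_head,left,3,2.09,90.5
regions,femoral_head,left,4,1.92,92.5
regions,femoral_head,left,5,1.46,93.9
regions,tibia,left,1,94.7,94.7
regions,tibia,left,2,4.18,98.9
regions,tibia,left,3,0.61,99.5
regions,tibia,left,4,0.15,99.7
regions,tibia,left,5,0.1,99.8
regions,tibia_plateau,left,1,78.9,78.9
regions,tibia_plateau,left,2,9.13,88
regions,tibia_plateau,left,3,4.79,92.8
regions,tibia_plateau,left,4,2.03,94.9
regions,tibia_plateau,left,5,1.22,96.1
regions,patella,left,1,73.3,73.3
regions,patella,left,2,10.8,84.1
regions,patella,left,3,5.93,90
regions,patella,left,4,2.4,92.4
regions,patella,left,5,1.39,93.8
regions,femur_condyles,right,1,67.3,67.3
regions,femur_condyles,right,2,25.6,92.9
regions,femur_condyles,right,3,2.66,95.5
regions,femur_condyles,right,4,1.65,97.2
regions,femur_condyles,right,5,0.81,98.0
regions,femoral_head,right,1,83.4,83.4
regions,femoral_head,right,2,5.12,88.5
regions,femoral_head,right,3,2.35,90.8
regions,femoral_head,right,4,1.87,92.7
regions,femoral_head,right,5,1.43,94.1
regions,tibia,right,1,97.6,97.6
regions,tibia,right,2,1.82,99.4
regions,tibia,right,3,0.2,99.6
regions,tibia,right,4,0.09,99.7
regions,tibia,right,5,0.07,99.8
regions,tibia_plateau,right,1,77.6,77.6
regions,tibia_plateau,right,2,11.3,88.8
regions,tibia_plateau,right,3,4.48,93.3
regions,tibia_plateau,right,4,1.72,95
regions,tibia_plateau,right,5,1.03,96.1
regions,patella,right,1,75.3,75.3
regions,patella,right,2,9.07,84.4
regions,patella,right,3,5.06,89.5
regions,patella,right,4,2.47,91.9
regions,patella,right,5,1.82,93.7
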