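athlete,discipline,marker,test1,test2,reported_change
A,swim,s_l200,1.37,1.39,1.4
A,swim,lt2_speed,1.28,1.32,2.6
A,swim,lt1_speed,1.22,1.25,2.5
A,swim,hr_max,184,184,0.0
A,bike,vo2max,59.8,63.9,6.9
A,bike,w_vo2max,260,280,7.7
A,bike,w_vt2,200,215,7.5
A,bike,w_vt1,155,170,9.7
A,bike,wkg_vo2max,5.3,5.9,12.5
A,bike,wkg_vt2,4.1,4.6,12.3
A,bike,wkg_vt1,3.1,3.6,14.6
A,bike,hr_max,181,182,0.6
A,run,vo2max,60.3,64.6,7.1
A,run,s_vo2max,17.2,18.1,5.2
A,run,s_vt2,15.1,16.3,7.9
A,run,s_vt1,13.3,13.9,4.5
A,run,hr_max,186,188,1.1
B,swim,s_l200,1.35,1.39,2.8
B,swim,lt2_speed,1.25,1.30,3.9
B,swim,lt1_speed,1.16,1.19,2.4
B,swim,hr_max,184,187,1.6
B,bike,vo2max,60.7,66.8,10.0
B,bike,w_vo2max,290,315,8.6
B,bike,w_vt2,240,260,8.3
B,bike,w_vt1,175,195,11.4
B,bike,wkg_vo2max,4.7,5.3,12.2
B,bike,wkg_vt2,3.9,4.3,12.0
B,bike,wkg_vt1,2.8,3.3,15.0
B,bike,hr_max,187,187,0.0
B,run,vo2max,59.4,64.8,9.1
B,run,s_vo2max,16.9,17.8,5.3
B,run,s_vt2,14.5,15.4,6.2
B,run,s_vt1,13.0,13.3,2.3
B,run,hr_max,191,195,2.1
C,swim,s_l200,1.41,1.43,1.4
C,swim,lt2_speed,1.28,1.33,4.0
C,swim,lt1_speed,1.22,1.23,1.2
C,swim,hr_max,184,186,1.1
C,bike,vo2max,61.3,66.2,8.0
C,bike,w_vo2max,290,315,8.6
C,bike,w_vt2,230,250,8.7
C,bike,w_vt1,160,190,18.8
C,bike,wkg_vo2max,4.8,5.2,8.4
C,bike,wkg_vt2,3.8,4.1,8.5
C,bike,wkg_vt1,2.6,3.1,18.6
C,bike,hr_max,183,182,-0.5
C,run,vo2max,63.1,67.5,7.0
C,run,s_vo2max,17.5,18.4,5.1
C,run,s_vt2,14.8,16.0,8.1
C,run,s_vt1,13.0,13.6,4.6
C,run,hr_max,193,197,2.1
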