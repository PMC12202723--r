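"tr_pcasl","b1_ave","g_max","g_ave","t_rf","status"
500,0.1,5.5,0.7,250,"included"
500,0.1,6,0.7,250,"included"
500,0.1,7,1,250,"slew_excluded"
500,0.1,8,0,250,"slew_excluded"
500,0.1,8,2,250,"included"
500,0.1,14,1.8,250,"slew_excluded"
500,0.3,4.5,0.8,250,"static_excluded"
500,0.4,3,1,250,"static_excluded"
500,0.4,8,0.3,250,"slew_excluded"
500,0.4,8,1.6,250,"slew_excluded"
500,0.4,10.5,1.6,250,"slew_excluded"
500,0.4,15,0.6,250,"slew_excluded"
500,0.5,7.5,0,250,"slew_excluded"
500,0.6,5,1.7,250,"static_excluded"
500,0.6,11.5,0.1,250,"slew_excluded"
500,0.7,6,1.9,250,"static_excluded"
500,0.7,14.5,1.3,250,"slew_excluded"
500,0.8,6,1.6,250,"static_excluded"
500,0.8,7,1.5,250,"static_excluded"
500,0.9,12,0.3,250,"slew_excluded"
500,1,5,1.6,250,"static_excluded"
500,1.1,6,0.2,250,"static_excluded"
500,1.1,11.5,1.6,250,"slew_excluded"
500,1.2,7.5,0.2,250,"slew_excluded"
500,1.2,12.5,1.6,250,"slew_excluded"
500,1.3,6.5,0.5,250,"slew_excluded"
500,1.3,9,0.6,250,"slew_excluded"
500,1.4,6,0.1,250,"static_excluded"
500,1.4,7,1.4,250,"static_excluded"
500,1.4,11,0.6,250,"slew_excluded"
500,1.5,7.5,0.4,250,"slew_excluded"
500,1.6,4,0,250,"static_excluded"
500,1.6,10,1.5,250,"slew_excluded"
500,1.6,11.5,0.4,250,"slew_excluded"
500,1.6,12.5,0.6,250,"slew_excluded"
500,1.7,13,1.5,250,"slew_excluded"
500,1.8,3.5,1.1,250,"static_excluded"
500,1.8,4.5,0.9,250,"static_excluded"
500,1.8,13,0.9,250,"slew_excluded"
500,1.9,7,1,250,"slew_excluded"
500,1.9,10,0.1,250,"slew_excluded"
600,0.1,4.5,0.8,300,"static_excluded"
600,0.1,7,1.7,300,"included"
600,0.2,4,1.7,300,"static_excluded"
600,0.2,7.5,0.4,300,"included"
600,0.2,7.5,1.4,300,"static_excluded"
600,0.2,8.5,1.9,300,"static_excluded"
600,0.2,10,0.5,300,"slew_excluded"
600,0.3,8,1,300,"included"
600,0.3,10.5,1.6,300,"slew_excluded"
600,0.3,12,1.6,300,"slew_excluded"
600,0.4,12,1.8,300,"slew_excluded"
600,0.6,13.5,1.5,300,"slew_excluded"
600,0.8,8.5,1,300,"slew_excluded"
600,0.8,13,2,300,"slew_excluded"
600,0.9,8,0.8,300,"static_excluded"
600,1,7.5,1.9,300,"static_excluded"
600,1,8,1,300,"static_excluded"
600,1,8.5,0.9,300,"slew_excluded"
600,1,9.5,0.9,300,"slew_excluded"
600,1,13,1.7,300,"slew_excluded"
600,1.1,13.5,2,300,"slew_excluded"
600,1.4,5.5,0.4,300,"static_excluded"
600,1.4,6,1.7,300,"static_excluded"
600,1.4,7,1.1,300,"static_excluded"
600,1.4,8,1.4,300,"static_excluded"
600,1.4,14,1.6,300,"slew_excluded"
600,1.4,15,0.7,300,"slew_excluded"
600,1.5,6.5,1,300,"static_excluded"
600,1.5,9,1.9,300,"slew_excluded"
600,1.6,5,1.5,300,"static_excluded"
600,1.6,11.5,0.6,300,"slew_excluded"
600,1.6,13,1.7,300,"slew_excluded"
600,1.7,7,0.6,300,"static_excluded"
600,1.7,10.5,1.3,300,"slew_excluded"
600,1.7,14.5,1,300,"slew_excluded"
600,1.8,4,1.2,300,"static_excluded"
600,1.8,4,1.9,300,"static_excluded"
600,1.8,14.5,0,300,"slew_excluded"
600,1.9,6.5,0.4,300,"static_excluded"
600,1.9,10.5,0.5,300,"slew_excluded"
600,1.9,11,1.5,300,"slew_excluded"
600,1.9,14,1.7,300,"slew_excluded"
700,0.1,5.5,1.2,350,"static_excluded"
700,0.1,7,0.4,350,"included"
700,0.1,8,0.4,350,"included"
700,0.1,8.5,1.2,350,"included"
700,0.2,11.5,0.3,350,"slew_excluded"
700,0.3,12.5,0.5,350,"slew_excluded"
700,0.4,7,0.3,350,"static_excluded"
700,0.4,8.5,1,350,"static_excluded"
700,0.5,10.5,1,350,"slew_excluded"
700,0.5,12.5,0.4,350,"slew_excluded"
700,0.6,8.5,1.7,350,"static_excluded"
700,0.6,10,1.5,350,"static_excluded"
700,0.7,10,0.3,350,"slew_excluded"
700,0.8,9.5,0.9,350,"slew_excluded"
700,0.8,11,1.1,350,"slew_excluded"
700,0.9,5,1.6,350,"static_excluded"
700,0.9,13,1.6,350,"slew_excluded"
700,1,9,1.5,350,"static_excluded"
700,1.1,5.5,0.8,350,"static_excluded"
700,1.1,6,0.9,350,"static_excluded"
700,1.1,11.5,1.8,350,"slew_excluded"
700,1.1,13,1.1,350,"slew_excluded"
700,1.2,7,0.8,350,"static_excluded"
700,1.2,8.5,1.7,350,"static_excluded"
700,1.2,10,1.1,350,"slew_excluded"
700,1.2,12.5,1.4,350,"slew_excluded"
700,1.3,12.5,0.8,350,"slew_excluded"
700,1.5,14,0.5,350,"slew_excluded"
700,1.6,5.5,1.5,350,"static_excluded"
700,1.6,14,1.2,350,"slew_excluded"
700,1.7,3.5,0.3,350,"static_excluded"
700,1.7,5,1.6,350,"static_excluded"
700,1.7,7.5,0.5,350,"static_excluded"
700,1.7,14,0.2,350,"slew_excluded"
700,1.8,4.5,0.3,350,"static_excluded"
700,1.8,13.5,1.7,350,"slew_excluded"
700,1.9,6,1.8,350,"static_excluded"
700,1.9,7.5,2,350,"static_excluded"
700,1.9,14.5,0.1,350,"slew_excluded"
700,2,6,0.3,350,"static_excluded"
700,2,8,1.4,350,"static_excluded"
800,0.2,4,2,400,"static_excluded"
800,0.2,5.5,1.8,400,"static_excluded"
800,0.2,13.5,0.1,400,"slew_excluded"
800,0.3,7,1.4,400,"static_excluded"
800,0.3,8,1.1,400,"included"
800,0.3,11,1,400,"slew_excluded"
800,0.3,11.5,0.9,400,"slew_excluded"
800,0.4,5,2,400,"static_excluded"
800,0.4,14,0.4,400,"slew_excluded"
800,0.4,14.5,1.5,400,"slew_excluded"
800,0.5,5,0,400,"static_excluded"
800,0.5,11.5,1.9,400,"included"
800,0.6,12.5,1.3,400,"slew_excluded"
800,0.7,6,0.3,400,"static_excluded"
800,0.7,10,0.2,400,"included"
800,0.9,3.5,0.4,400,"static_excluded"
800,1,4.5,1.1,400,"static_excluded"
800,1,5.5,0.3,400,"static_excluded"
800,1,15,1.9,400,"slew_excluded"
800,1.1,4,1.2,400,"static_excluded"
800,1.1,13,1.8,400,"slew_excluded"
800,1.1,13.5,0.5,400,"slew_excluded"
800,1.2,6.5,1.5,400,"static_excluded"
800,1.2,7.5,1.5,400,"static_excluded"
800,1.3,3.5,0.1,400,"static_excluded"
800,1.3,6.5,1.5,400,"static_excluded"
800,1.4,13.5,1.4,400,"slew_excluded"
800,1.5,6.5,0.5,400,"static_excluded"
800,1.5,14,1.9,400,"slew_excluded"
800,1.6,9.5,1.1,400,"static_excluded"
800,1.6,13.5,0,400,"slew_excluded"
800,1.6,15,1.6,400,"slew_excluded"
800,1.7,11,0.2,400,"slew_excluded"
800,1.8,7,1,400,"static_excluded"
800,1.8,8,1.3,400,"static_excluded"
800,1.8,9,0.7,400,"static_excluded"
800,2,7.5,1.7,400,"static_excluded"
800,2,9,2,400,"static_excluded"
1060,0.1,7.5,0.4,530,"included"
1060,0.1,14,1.2,530,"included"
1060,0.2,3.5,1.1,530,"static_excluded"
1060,0.2,4.5,1.5,530,"static_excluded"
1060,0.2,7.5,1.2,530,"included"
1060,0.2,8,1.4,530,"included"
1060,0.2,10,1.1,530,"included"
1060,0.3,8,1.3,530,"included"
1060,0.5,5.5,0.2,530,"included"
1060,0.5,14.5,0.2,530,"slew_excluded"
1060,0.6,5,0.6,530,"static_excluded"
1060,0.6,14,0.6,530,"slew_excluded"
1060,0.6,14,1.6,530,"included"
1060,0.7,9,2,530,"static_excluded"
1060,0.7,10.5,0.4,530,"included"
1060,0.8,4,0.8,530,"static_excluded"
1060,0.8,7,1.1,530,"static_excluded"
1060,0.9,6,0,530,"static_excluded"
1060,0.9,15,0.2,530,"slew_excluded"
1060,1,11,0.9,530,"included"
1060,1.2,5.5,0.9,530,"static_excluded"
1060,1.2,6,1.5,530,"included"
1060,1.2,9.5,1.2,530,"included"
1060,1.3,3,0,530,"static_excluded"
1060,1.3,6.5,0.6,530,"static_excluded"
1060,1.3,10.5,0.2,530,"included"
1060,1.3,13.5,0.6,530,"static_excluded"
1060,1.4,11,1,530,"static_excluded"
1060,1.4,11,1.8,530,"static_excluded"
1060,1.5,9,0.4,530,"static_excluded"
1060,1.5,13,0.7,530,"static_excluded"
1060,1.5,14,0.5,530,"slew_excluded"
1060,1.9,5,1.5,530,"static_excluded"
1060,1.9,7,0.7,530,"static_excluded"
1060,1.9,8,0.1,530,"static_excluded"
1060,1.9,10,1.1,530,"static_excluded"
1060,2,6,0.3,530,"included"
1060,2,9,0.3,530,"static_excluded"
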