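item,mean,sd,pct0,pct1,pct2,pct3,pct4,pct5,pct6,pct7,pct8,pct9,pct10
total_pay,6.73,2.41,1.9,1.6,3.2,4.9,5.1,10.8,10.0,18.5,21.4,9.7,12.8
job_security,7.72,2.50,1.9,1.5,2.5,2.9,2.9,7.1,4.6,10.0,18.6,17.6,30.8
work_itself,7.67,2.06,0.5,0.7,1.4,2.4,2.6,7.3,7.7,15.2,23.6,17.5,21.1
working_hours,7.14,2.35,1.0,1.4,2.7,3.9,4.3,10.8,8.7,15.1,20.8,13.3,18.0
flexibility,7.36,2.60,2.0,1.7,3.2,3.8,3.8,8.5,6.3,11.6,18.0,15.0,26.0
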