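measure,test,order,group,mean,sd,n,printed_statistic,printed_df1,printed_df2
age,anova,1,never,53.09,4.96,33,1.76,2,78
age,anova,2,past,54.64,6.48,28,1.76,2,78
age,anova,3,smoker,56.30,7.12,20,1.76,2,78
income,anova,1,never,3.15,1.25,33,0.37,2,78
income,anova,2,past,3.14,1.41,28,0.37,2,78
income,anova,3,smoker,2.85,1.42,20,0.37,2,78
kbdi,anova,1,never,8.63,6.89,33,0.35,2,78
kbdi,anova,2,past,9.96,6.50,28,0.35,2,78
kbdi,anova,3,smoker,8.75,6.27,20,0.35,2,78
initiation_age,t,1,past,19.43,1.32,28,-2.95,46,
initiation_age,t,2,smoker,18.10,1.80,20,-2.95,46,
years_smoking,t,1,past,10.21,6.43,28,13.63,46,
years_smoking,t,2,smoker,37.80,7.54,20,13.63,46,
cigarettes_per_day,t,1,past,18.24,9.05,21,-0.90,38,
cigarettes_per_day,t,2,smoker,20.53,6.76,19,-0.90,38,
ftnd,t,1,past,3.15,3.17,20,2.81,37,
ftnd,t,2,smoker,5.58,2.09,19,2.81,37,
qsu,t,1,past,10.80,2.73,20,4.46,37,
qsu,t,2,smoker,21.32,10.17,19,4.46,37,
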